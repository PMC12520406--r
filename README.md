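# myograph

Graph-based detection of z-discs, sarcomeres, and myofibrils in
single-cell fluorescence images of cardiomyocytes, with per-cell
structural-organization scoring.

Human iPSC-derived cardiomyocytes (hiPSC-CMs) mature from cells whose
alpha-actinin channel shows mostly round puncta (z-bodies) into cells
with regularly spaced, aligned z-disc bands. Quantifying that maturation
requires detecting *individual* sarcomeres — the ~13 px segments between
consecutive z-discs along a myofibril — rather than image-level texture
averages. The hard part is that immature cells are full of bright
objects that are not z-discs.

## Method

**Z-disc segmentation.** Laplacian-of-Gaussian filtering → Otsu
thresholding → marching-squares contour extraction → perimeter gate
([15, 200] px) → a pluggable pair of crop classifiers (one
intensity-preserving input type, one intensity-invariant), whose averaged
probability must reach 0.3 → sub-pixel peak localization by bounded
multi-start gradient ascent, splitting merged contours when a secondary
peak reaches 60% of the primary.

**Sarcomere detection.** Z-discs become nodes of a mutual k-nearest-
neighbor graph; every candidate edge *i* receives four scores in [0, 1]:

- the local score
  `S_i = 1{l_min < l_i < l_max} ( max_j [c1 f1(θ_ij) + c2 f2(l_i, l_j)] + c3 f3(l_i) )`
  with `f1(θ) = 1{θ ≤ π/2} (1 − θ/(π/2))²`,
  `f2(l_i, l_j) = (1 + |l_j − l_i|/l_i)⁻¹`,
  `f3(l) = exp(−π (1 − l/l_avg)²)` and `c1 = c2 = c3 = 1/3`;
- a pruning-validity score from a first pruning pass;
- the mean z-disc probability of the endpoints;
- a global-alignment score propagating "reach" along chains.

The four scores are fused by probabilistic ensemble averaging,

```
p(edge = sarcomere | s1..sn) = Π s_i / (Π s_i + Π (1 − s_i)),
```

pruned greedily under a degree-2-per-node cap, assembled into myofibril
chains, and extended across detection gaps with virtual z-discs
(7 px match radius, new sarcomere length in [10, 20] px, turn < 22.5°);
single-sarcomere myofibrils are dropped.

**Organization scoring.** Nine per-cell features (sarcomere length mean
and SD, nematic orientational order parameter, cell area, sarcomere and
myofibril counts, sarcomeres per myofibril, z-disc classification ratio,
probabilistic z-disc area) feed two heads: an RBF-kernel SVR
(C = 10, gamma = 0.1, epsilon = 0.5) regressing combined expert scores,
and an unsupervised k-means + mistake-minimizing threshold tree that
labels cells Low / Medium / High (zero-sarcomere cells are always Low).

A seeded synthetic-image generator with exact ground truth
(`generate_cell()`) makes every stage testable without external data.

## Worked example

```r
library(myograph)

spec <- synthetic_cell_spec(n_myofibrils = 10, sarcomeres_per_myofibril = 8,
                            n_puncta = 50, seed = 3)
cell <- generate_cell(spec)
cell
#> Synthetic cardiomyocyte image 256 x 256
#>   z-discs: 90  puncta: 50  sarcomeres: 80  myofibrils: 10

# train the baseline classifier pair on synthetic labeled crops
lc <- generate_labeled_crops(synthetic_cell_spec(seed = 42), n_per_class = 200)
clf1 <- train_baseline_classifier(lc$crops, lc$labels, input_type = 1, seed = 1)
clf2 <- train_baseline_classifier(lc$crops, lc$labels, input_type = 2, seed = 1)

det <- detect_sarcomeres(cell, clf1, clf2,
                         config = sarc_config(min_contour_length = 6))
summary(det)
#> Sarcomere detection summary
#>   image: 256 x 256  Otsu threshold: 8.148
#>   contours after length filter: 133
#>   candidates >= 0.3: 81 of 133
#>   z-discs: 85 (1 secondary, 3 virtual)
#>   sarcomeres: 76 (66 before extension)
#>   sarcomere length: 12.98 +/- 0.98 px
#>   orientational order parameter: 0.960
#>   myofibrils: 8 (mean length 9.50 sarcomeres, max 20)

cell_features(det)
#> Cell structural features:
#>   avg_sarcomere_length         12.98
#>   sd_sarcomere_length          0.9817
#>   orientation_order_parameter  0.9598
#>   cell_area                    6.554e+04
#>   n_sarcomeres                 76
#>   n_myofibrils                 8
#>   avg_sarcomeres_per_myofibril 9.5
#>   zdisc_classification_ratio   0.4586
#>   probabilistic_zdisc_area     622
```

The generated cell contains 80 true sarcomeres in 10 myofibrils plus 50
decoy puncta; the classifier pair (held-out accuracy ~0.99 on crops)
discards the puncta, and the graph stage recovers 76 sarcomeres in 8
chains — 66 directly and 10 more via gap-bridging extension — at the
expected ~13 px length and with the high orientational order (0.96) of a
single-axis cell. `plot(det, image = cell$image)` overlays the detected
chains on the image, and `write_detection(det, dir)` writes the contour,
z-disc, sarcomere, and myofibril tables plus a run manifest as
CSV/JSON.

A thin command-line interface over the same functions is included at
`inst/cli/myograph.R` (subcommands `simulate`, `detect`, `features`,
`train-score`, `predict-score`, `cluster`).

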