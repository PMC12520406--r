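# Crop construction, the baseline classifier pair, probability averaging
# and filtering.

make_crop_scene <- function() {
  img <- render_blobs(100, 100, rbind(c(30, 30), c(70, 70)), c(5, 5),
                      c(2.5, 2.5), background = 0.1)
  filt <- log_filter(img, 1)
  cts <- extract_contours(filt)
  list(img = img, filt = filt, contours = cts)
}

test_that("single-contour crops have empty 'other contour' channels", {
  img <- render_blobs(100, 100, matrix(c(50, 50), 1), 5, 2.5)
  filt <- log_filter(img, 1)
  cts <- extract_contours(filt)
  expect_length(cts, 1)
  crop <- build_crop(img, cts, 1, filtered = filt)
  expect_true(all(crop$type1[, , 3] == 0))
  expect_true(all(crop$type2[, , 3] == 0))
  expect_true(all(crop$type2[, , 2] %in% c(0, 1)))
})

test_that("border crops are zero-padded to 128 x 128", {
  img <- render_blobs(60, 60, matrix(c(3, 3), 1), 5, 1.5)
  filt <- log_filter(img, 1)
  cts <- extract_contours(filt)
  crop <- build_crop(img, cts, 1, filtered = filt)
  expect_identical(dim(crop$type1), c(128L, 128L, 3L))
  # the part of the crop hanging off the image is zero
  expect_true(all(crop$type1[1:40, 1:40, 1] == 0))
})

test_that("the target channel is nonzero only inside the target polygon", {
  scene <- make_crop_scene()
  expect_length(scene$contours, 2)
  crop <- build_crop(scene$img, scene$contours, 1, filtered = scene$filt)
  ctr <- round(crop$centroid)
  nz <- which(crop$type1[, , 2] != 0, arr.ind = TRUE)
  # map crop pixels back to 0-based image coordinates
  global <- cbind(nz[, 1] - 1 + ctr[1] - 64, nz[, 2] - 1 + ctr[2] - 64)
  v <- scene$contours[[1]]$vertices
  inside <- pracma::inpolygon(global[, 1], global[, 2], v[, 1], v[, 2],
                              boundary = TRUE)
  expect_true(all(inside))
  # and the other-contours channel excludes the target's pixels
  expect_equal(sum(crop$type1[, , 2] * crop$type1[, , 3]), 0)
})

test_that("probability averaging is exact and commutative", {
  scene <- make_crop_scene()
  crops <- build_crops(scene$img, scene$contours, filtered = scene$filt)
  cand <- classify_candidates(crops, const_classifier(0.9),
                              const_classifier(0.7))
  expect_equal(cand$p_zdisc, rep(0.8, nrow(cand)))
  swapped <- classify_candidates(crops, const_classifier(0.7),
                                 const_classifier(0.9))
  expect_equal(cand$p_zdisc, swapped$p_zdisc)
  same <- classify_candidates(crops, const_classifier(0.42),
                              const_classifier(0.42))
  expect_equal(same$p_zdisc, rep(0.42, nrow(same)))
  half <- classify_candidates(crops, const_classifier(0.9),
                              const_classifier(0.5))
  expect_equal(half$p_zdisc, rep((0.9 + 0.5) / 2, nrow(half)))
})

test_that("classifier outputs outside [0, 1] violate the contract", {
  scene <- make_crop_scene()
  crops <- build_crops(scene$img, scene$contours, filtered = scene$filt)
  expect_error(classify_candidates(crops, const_classifier(1.5),
                                   const_classifier(0.5)),
               "contract")
})

test_that("probability filtering keeps the closed threshold and is monotone", {
  cand <- data.frame(contour_id = 1:3, p1 = 0, p2 = 0,
                     p_zdisc = c(0.29, 0.30, 0.95))
  expect_equal(filter_by_probability(cand)$p_zdisc, c(0.30, 0.95))
  expect_identical(filter_by_probability(cand, 0), cand)
  expect_equal(nrow(filter_by_probability(cand, 1)), 0)
  for (thr in seq(0, 1, by = 0.1)) {
    lo <- filter_by_probability(cand, thr)
    hi <- filter_by_probability(cand, min(1, thr + 0.1))
    expect_true(all(hi$contour_id %in% lo$contour_id))
  }
})

test_that("a separable toy problem is fit with training accuracy 1", {
  # two point masses in descriptor space: bright-interior vs dim-interior
  make_toy <- function(mean_in, n) {
    lapply(seq_len(n), function(i) {
      raw <- matrix(0.1, 16, 16)
      mask <- matrix(FALSE, 16, 16); mask[7:10, 7:10] <- TRUE
      raw[mask] <- mean_in
      structure(list(contour_id = i, centroid = c(8, 8),
                     type1 = array(c(raw, raw * mask, raw * 0),
                                   c(16, 16, 3)),
                     type2 = array(c(raw, mask, mask * 0), c(16, 16, 3)),
                     target_mask = mask,
                     perimeter = 16, area = 16,
                     vertices = cbind(row = c(6, 6, 10, 10),
                                      col = c(6, 10, 10, 6))),
                class = "contour_crop")
    })
  }
  crops <- c(make_toy(10, 10), make_toy(0.5, 10))
  labels <- rep(c("zdisc", "not_zdisc"), each = 10)
  # the degenerate fixture has constant descriptors and a tiny class:
  # both provoke expected warnings that are not the property under test
  clf <- suppressWarnings(
    train_baseline_classifier(crops, labels, input_type = 1, seed = 3))
  p <- predict(clf, crops)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean((p >= 0.5) == (labels == "zdisc")), 1)
})

test_that("degenerate label sets are rejected", {
  scene <- make_crop_scene()
  crops <- build_crops(scene$img, scene$contours, filtered = scene$filt)
  expect_error(train_baseline_classifier(crops, rep("zdisc", 2), 1),
               "single class")
  expect_error(train_baseline_classifier(c(crops, crops),
                                         c("zdisc", "zdisc", "zdisc",
                                           "not_zdisc"), 1),
               "2 examples")
})

test_that("trained pair suppresses puncta more than z-discs at 0.3", {
  spec <- synthetic_cell_spec(seed = 31)
  lc <- generate_labeled_crops(spec, n_per_class = 120)
  set.seed(8)
  idx <- sample(length(lc$crops))
  tr <- idx[seq_len(floor(length(idx) / 2))]
  te <- setdiff(idx, tr)
  c1 <- train_baseline_classifier(lc$crops[tr], lc$labels[tr], 1, seed = 8)
  c2 <- train_baseline_classifier(lc$crops[tr], lc$labels[tr], 2, seed = 8)
  cand <- classify_candidates(lc$crops[te], c1, c2)
  kept <- filter_by_probability(cand, 0.3)
  lab_te <- lc$labels[te]
  surv_z <- mean(cand$p_zdisc[lab_te == "zdisc"] >= 0.3)
  surv_p <- mean(cand$p_zdisc[lab_te == "not_zdisc"] >= 0.3)
  expect_gt(surv_z, surv_p)
  expect_true(all(kept$p_zdisc >= 0.3))
})

test_that("baseline classifiers survive a JSON round trip", {
  spec <- synthetic_cell_spec(seed = 17)
  lc <- generate_labeled_crops(spec, n_per_class = 30)
  clf <- train_baseline_classifier(lc$crops, lc$labels, input_type = 2,
                                   seed = 1)
  path <- tempfile(fileext = ".json")
  save_classifier(clf, path)
  clf2 <- load_classifier(path)
  expect_equal(predict(clf2, lc$crops), predict(clf, lc$crops),
               tolerance = 1e-10)
})
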