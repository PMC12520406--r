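# Mutual-kNN graph construction, the four edge scores, probabilistic
# ensemble averaging, and pruning.

test_that("two z-discs always form one mutual edge", {
  g <- build_candidate_graph(zdisc_table(rbind(c(0, 0), c(0, 13))), 3)
  expect_identical(nrow(g$edges), 1L)
  expect_equal(g$edges$length, 13)
})

test_that("the graph equals the brute-force mutual-kNN oracle", {
  set.seed(10)
  for (rep in 1:8) {
    n <- sample(5:30, 1)
    N <- sample(1:4, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    g <- build_candidate_graph(zdisc_table(pts), N)
    got <- g$edges[order(g$edges$a, g$edges$b), c("a", "b")]
    want <- mutual_knn_oracle(pts, N)
    expect_equal(unname(as.matrix(got)), unname(want))
  }
})

test_that("a single z-disc gives an empty graph with a warning", {
  expect_warning(g <- build_candidate_graph(zdisc_table(matrix(c(1, 1), 1))),
                 "fewer than 2")
  expect_identical(nrow(g$edges), 0L)
})

test_that("neighbor angles follow the collinear-zero convention", {
  nodes <- data.frame(row = c(0, 0, 0, 1, 1), col = c(0, 1, 2, 0, 1))
  # straight continuation: edges (1,2) and (2,3)
  expect_equal(neighbor_angle(c(1, 2), c(2, 3), nodes), 0)
  # doubling back: edges (1,2) and (2,1)-like via node 2 -> 1 reuse is
  # impossible; use (1,2) and (2,5)->? perpendicular instead:
  expect_equal(neighbor_angle(c(1, 2), c(2, 5), nodes), pi / 2)
  # equilateral corner, checked against an explicit dot-product oracle
  eq <- data.frame(row = c(0, 1, 0.5), col = c(0, 0, sqrt(3) / 2))
  u <- c(eq$row[2] - eq$row[1], eq$col[2] - eq$col[1])
  v <- c(eq$row[3] - eq$row[1], eq$col[3] - eq$col[1])
  oracle <- pi - acos(sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2))))
  expect_equal(neighbor_angle(c(1, 2), c(1, 3), eq), oracle)
  expect_error(neighbor_angle(c(1, 2), c(3, 4), nodes), "share")
})

test_that("the scoring kernels hit their closed-form values", {
  f1 <- myograph:::f_angle
  f2 <- myograph:::f_length_consistency
  f3 <- myograph:::f_length_prior
  expect_equal(f1(0), 1)
  expect_equal(f1(pi / 2), 0)
  expect_equal(f1(pi / 4), 0.25)
  expect_equal(f1(3), 0)           # beyond pi/2
  expect_equal(f2(15, 15), 1)
  expect_equal(f2(10, 15), 1 / 1.5)
  expect_equal(f3(15, 15), 1)
})

test_that("the original score matches hand-derived fixtures", {
  cfg <- scoring_config()
  # isolated edge of average length: only the c3 term
  iso <- structure(list(nodes = zdisc_table(rbind(c(0, 0), c(0, 15))),
                        edges = data.frame(a = 1L, b = 2L, length = 15,
                                           orientation = 0)),
                   class = "sarc_graph")
  expect_equal(score_original(iso, cfg), 1 / 3, tolerance = 1e-12)

  # two collinear equal-length edges: perfect score
  g2 <- structure(list(
    nodes = zdisc_table(rbind(c(0, 0), c(0, 15), c(0, 30))),
    edges = data.frame(a = c(1L, 2L), b = c(2L, 3L), length = 15,
                       orientation = 0)),
    class = "sarc_graph")
  expect_equal(score_original(g2, cfg), c(1, 1), tolerance = 1e-12)

  # neighbor at 45 degrees, equal lengths
  p3 <- rbind(c(0, 15), c(0, 0),
              c(15 * sin(3 * pi / 4), 15 * cos(3 * pi / 4)))
  g3 <- structure(list(nodes = zdisc_table(p3),
                       edges = data.frame(
                         a = c(2L, 2L), b = c(1L, 3L), length = c(15, 15),
                         orientation = c(0, pi * 3 / 4))),
                  class = "sarc_graph")
  s <- score_original(g3, cfg)
  expect_equal(s[1], (1 / 3) * 0.25 + 1 / 3 + 1 / 3, tolerance = 1e-12)

  # length outside (l_min, l_max) scores zero
  far <- structure(list(nodes = zdisc_table(rbind(c(0, 0), c(0, 25))),
                        edges = data.frame(a = 1L, b = 2L, length = 25,
                                           orientation = 0)),
                   class = "sarc_graph")
  expect_equal(score_original(far, cfg), 0)
  edge_at <- function(l) structure(
    list(nodes = zdisc_table(rbind(c(0, 0), c(0, l))),
         edges = data.frame(a = 1L, b = 2L, length = l, orientation = 0)),
    class = "sarc_graph")
  expect_equal(score_original(edge_at(10), cfg), 0)   # boundary is excluded
  expect_equal(score_original(edge_at(20), cfg), 0)
})

test_that("z-disc probability scoring averages the endpoints", {
  g <- build_candidate_graph(zdisc_table(rbind(c(0, 0), c(0, 13)),
                                         p = c(1, 0.5)), 2)
  expect_equal(score_zdisc_probability(g), 0.75)
  g0 <- build_candidate_graph(zdisc_table(rbind(c(0, 0), c(0, 13)),
                                          p = c(0, 0)), 2)
  expect_equal(score_zdisc_probability(g0), 0)
  grev <- build_candidate_graph(zdisc_table(rbind(c(0, 13), c(0, 0)),
                                            p = c(0.5, 1)), 2)
  expect_equal(score_zdisc_probability(grev), 0.75)
})

test_that("pruning validity maps to exactly three score levels", {
  set.seed(77)
  pts <- chain_positions(8, 13)
  pts <- rbind(pts, pts + matrix(rep(c(40, 3), each = 8), ncol = 2))
  g <- build_candidate_graph(zdisc_table(pts), 4)
  cfg <- scoring_config()
  sv <- score_pruning_validity(g, cfg)
  expect_true(all(sv %in% c(cfg$epsilon_clip, 0.5, 1 - cfg$epsilon_clip)))
  s_orig <- score_original(g, cfg)
  pr <- prune_graph(g, s_orig, cfg$s_accept, cfg$s_strong)
  expect_equal(sv, c(cfg$epsilon_clip, 0.5,
                     1 - cfg$epsilon_clip)[pr$validity + 1L])
})

test_that("global alignment scoring follows the reach recursion", {
  cfg <- scoring_config()
  # isolated edge
  iso <- structure(list(nodes = zdisc_table(rbind(c(0, 0), c(0, 15))),
                        edges = data.frame(a = 1L, b = 2L, length = 15,
                                           orientation = 0)),
                   class = "sarc_graph")
  expect_equal(score_global_alignment(iso, cfg), 0)

  # long straight chain: interior edges saturate at 1
  g <- build_candidate_graph(zdisc_table(chain_positions(12, 15)), 2)
  s <- score_global_alignment(g, cfg)
  interior <- which(pmin(g$edges$a, g$edges$b) > 5 &
                      pmax(g$edges$a, g$edges$b) < 8)
  expect_equal(s[interior], rep(1, length(interior)), tolerance = 1e-12)

  # three-edge chain: terminal edge scores (0 + 2) / (2 * 5)
  g3 <- build_candidate_graph(zdisc_table(chain_positions(4, 15)), 2)
  s3 <- score_global_alignment(g3, cfg)
  terminal <- which(g3$edges$a == 1 | g3$edges$b == 1)
  expect_equal(s3[terminal], 0.2, tolerance = 1e-12)

  # brute-force recursive enumeration oracle on the same 3-edge graph
  E <- g3$edges
  reach <- function(e, node, t) {
    if (t == 0) return(0)
    nbrs <- setdiff(which(E$a == node | E$b == node), e)
    if (!length(nbrs)) return(0)
    max(vapply(nbrs, function(e2) {
      th <- neighbor_angle(c(E$a[e], E$b[e]), c(E$a[e2], E$b[e2]), g3$nodes)
      w <- myograph:::f_angle(th) *
        myograph:::f_length_consistency(E$length[e], E$length[e2])
      far <- if (E$a[e2] == node) E$b[e2] else E$a[e2]
      w * (1 + reach(e2, far, t - 1))
    }, numeric(1)))
  }
  for (e in seq_len(nrow(E))) {
    want <- (reach(e, E$a[e], 5) + reach(e, E$b[e], 5)) / 10
    expect_equal(s3[e], min(1, want), tolerance = 1e-12)
  }
})

test_that("probabilistic ensemble averaging obeys its algebra", {
  cfg <- scoring_config()
  # single-method identity
  expect_equal(ensemble_scores(matrix(0.7, 1, 1), cfg), 0.7)
  # hand evaluation for two scores of 0.8
  expect_equal(ensemble_scores(matrix(c(0.8, 0.8), 1, 2), cfg),
               0.64 / (0.64 + 0.04), tolerance = 1e-12)
  # all-0.5 symmetry
  expect_equal(ensemble_scores(matrix(0.5, 1, 4), cfg), 0.5)
  # direct product-formula oracle, 1000 random vectors
  set.seed(99)
  max_err <- 0
  for (rep in 1:1000) {
    n <- sample(1:6, 1)
    s <- runif(n, cfg$epsilon_clip, 1 - cfg$epsilon_clip)
    direct <- prod(s) / (prod(s) + prod(1 - s))
    direct_c <- prod(1 - s) / (prod(1 - s) + prod(s))   # complement
    max_err <- max(max_err,
                   abs(ensemble_scores(matrix(s, 1), cfg) - direct),
                   abs(ensemble_scores(matrix(1 - s, 1), cfg) - direct_c))
  }
  expect_lt(max_err, 1e-12)
  # monotone in each component
  set.seed(100)
  for (rep in 1:50) {
    s <- runif(4, 0.05, 0.9)
    base <- ensemble_scores(matrix(s, 1), cfg)
    for (i in 1:4) {
      s2 <- s; s2[i] <- s2[i] + 0.05
      expect_gte(ensemble_scores(matrix(s2, 1), cfg), base)
    }
  }
  # general prior: direct two-hypothesis normalization oracle
  cfg2 <- scoring_config(pi0 = 0.3)
  s <- c(0.8, 0.6, 0.4)
  num <- prod(s) / 0.3^2
  den <- prod(1 - s) / 0.7^2
  expect_equal(ensemble_scores(matrix(s, 1), cfg2), num / (num + den),
               tolerance = 1e-12)
})

test_that("greedy pruning respects the degree cap and thresholds", {
  # star of four edges at node 1
  pts <- rbind(c(0, 0), c(0, 13), c(13, 0), c(0, -13), c(-13, 0))
  g <- structure(list(nodes = zdisc_table(pts),
                      edges = data.frame(a = rep(1L, 4), b = 2:5,
                                         length = 13, orientation = 0)),
                 class = "sarc_graph")
  pr <- prune_graph(g, c(0.9, 0.8, 0.7, 0.6))
  expect_identical(pr$validity, c(2L, 2L, 0L, 0L))
  expect_identical(sum(pr$retained), 2L)

  expect_identical(sum(prune_graph(g, c(0.4, 0.3, 0.2, 0.1))$retained), 0L)

  chain <- build_candidate_graph(zdisc_table(chain_positions(6, 13)), 2)
  prc <- prune_graph(chain, rep(0.9, nrow(chain$edges)))
  expect_true(all(prc$retained))
  deg <- table(c(chain$edges$a, chain$edges$b)[rep(prc$retained, 2)])
  expect_true(all(deg <= 2))
})

test_that("myofibril assembly returns ordered simple paths", {
  chain <- build_candidate_graph(zdisc_table(chain_positions(5, 13)), 2)
  sc <- rep(0.9, nrow(chain$edges))
  pr <- prune_graph(chain, sc)
  myos <- assemble_myofibrils(chain, pr$retained, sc)
  expect_length(myos, 1)
  expect_length(myos[[1]], 5)
  expect_identical(anyDuplicated(myos[[1]]), 0L)

  # five-node cycle: broken at the weakest edge
  ring <- structure(list(
    nodes = zdisc_table(cbind(10 * cos(2 * pi * (0:4) / 5),
                              10 * sin(2 * pi * (0:4) / 5))),
    edges = data.frame(a = 1:5, b = c(2:5, 1L), length = 11.76,
                       orientation = 0)),
    class = "sarc_graph")
  sc <- c(0.9, 0.8, 0.95, 0.85, 0.7)
  myos <- assemble_myofibrils(ring, rep(TRUE, 5), sc)
  expect_length(myos, 1)
  expect_length(myos[[1]], 5)
  # the weakest edge (5,1) is the one missing
  steps <- cbind(myos[[1]][-5], myos[[1]][-1])
  keys <- paste(pmin(steps[, 1], steps[, 2]), pmax(steps[, 1], steps[, 2]))
  expect_false("1 5" %in% keys)

  expect_length(assemble_myofibrils(ring, rep(FALSE, 5), sc), 0)
})

test_that("random configurations keep degree <= 2 and disjoint paths", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(5:25, 1)
    pts <- cbind(runif(n, 0, 80), runif(n, 0, 80))
    g <- build_candidate_graph(zdisc_table(pts, p = runif(n)), 3)
    if (nrow(g$edges) == 0) next
    sc <- ensemble_scores(cbind(score_original(g),
                                score_zdisc_probability(g),
                                score_global_alignment(g)))
    pr <- prune_graph(g, sc)
    kept <- g$edges[pr$retained, , drop = FALSE]
    if (nrow(kept) == 0) next
    deg <- table(c(kept$a, kept$b))
    expect_true(all(deg <= 2))
    myos <- assemble_myofibrils(g, pr$retained, sc)
    all_nodes <- unlist(myos)
    expect_identical(anyDuplicated(all_nodes), 0L)
    for (ch in myos) expect_identical(anyDuplicated(ch), 0L)
  }
})
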