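# Supervised SVR scoring head and unsupervised k-means + threshold tree.

# Synthetic cohort: organization driven by sarcomere density with noise.
make_cohort <- function(n, seed) {
  set.seed(seed)
  dens <- runif(n, 0, 0.02)
  X <- cbind(
    avg_sarcomere_length = rnorm(n, 13, 1),
    sd_sarcomere_length = runif(n, 0, 2),
    orientation_order_parameter = pmin(1, pmax(0, dens * 40 + rnorm(n, 0, 0.1))),
    sarcomere_density = dens,
    myofibril_density = dens / 8 + rnorm(n, 0, 5e-4),
    avg_sarcomeres_per_myofibril = 2 + dens * 300 + rnorm(n, 0, 0.5),
    zdisc_classification_ratio = pmin(1, pmax(0, dens * 45 + rnorm(n, 0, 0.08))),
    prob_zdisc_area_fraction = pmin(1, dens * 10 + abs(rnorm(n, 0, 0.01)))
  )
  combined <- pmin(9, pmax(1, 1 + 400 * dens + rnorm(n, 0, 0.6)))
  list(X = X, combined = combined, density = dens)
}

test_that("the SVR head recovers a monotone organization signal", {
  co <- make_cohort(500, seed = 71)
  tr <- 1:400; te <- 401:500
  reg <- train_score_regressor(co$X[tr, ], combined = co$combined[tr])
  pred_tr <- predict_scores(reg, co$X[tr, ])
  expect_true(all(is.finite(pred_tr)))
  expect_gt(cor(pred_tr, co$combined[tr]), 0)
  pred_te <- predict_scores(reg, co$X[te, ])
  expect_gte(cor(pred_te, (co$combined[te] + 1) / 2), 0.9)
  expect_true(all(pred_te >= 1 & pred_te <= 5))
})

test_that("standardization round-trips and drops constant features", {
  co <- make_cohort(50, seed = 5)
  std <- myograph:::standardizer_fit(co$X)
  Xs <- myograph:::standardizer_apply(std, co$X)
  back <- myograph:::standardizer_invert(std, Xs)
  expect_equal(unname(back), unname(co$X[, std$keep]), tolerance = 1e-10,
               ignore_attr = TRUE)
  Xc <- cbind(co$X, flat = rep(2, 50))
  expect_warning(std2 <- myograph:::standardizer_fit(Xc), "zero-variance")
  expect_false("flat" %in% std2$keep)
})

test_that("score rescaling maps the combined-scale endpoints to 1 and 5", {
  expect_equal(rescale_combined_score(9), 5)
  expect_equal(rescale_combined_score(1), 1)
  expect_equal(rescale_combined_score(11), 5)   # clipped
  expect_equal(rescale_combined_score(0), 1)    # clipped
  expect_equal(rescale_combined_score(5), 3)
  # predict_scores applies exactly this map to its raw predictions
  co <- make_cohort(60, seed = 8)
  reg <- train_score_regressor(co$X, combined = co$combined)
  sc <- predict_scores(reg, co$X)
  expect_equal(as.numeric(sc), rescale_combined_score(attr(sc, "raw")))
})

test_that("training guards reject degenerate inputs", {
  co <- make_cohort(20, seed = 9)
  expect_error(train_score_regressor(co$X[1:5, ], combined = rep(3, 5)),
               "at least 10")
  expect_error(train_score_regressor(co$X, combined = rep(3, 10)),
               "lengths differ")
  expect_error(train_score_regressor(co$X), "supply")
})

test_that("seeded k-means separates point masses reproducibly", {
  set.seed(31)
  X <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
             matrix(rnorm(60, 10, 0.1), ncol = 2),
             matrix(rnorm(60, 20, 0.1), ncol = 2))
  km <- kmeans_cluster(X, k = 3, seed = 4)
  expect_identical(km$labels, kmeans_cluster(X, k = 3, seed = 4)$labels)
  truth <- rep(1:3, each = 30)
  expect_equal(length(unique(paste(truth, km$labels))), 3L)
  # k-means cost beats 100 random assignments
  cost <- function(lab) {
    sum(vapply(unique(lab), function(g) {
      sub <- X[lab == g, , drop = FALSE]
      sum(scale(sub, scale = FALSE)^2)
    }, numeric(1)))
  }
  set.seed(7)
  rand_costs <- replicate(100, cost(sample(1:3, nrow(X), replace = TRUE)))
  expect_true(all(km$tot_withinss <= rand_costs))
  expect_error(kmeans_cluster(X[1:2, ], k = 3), "at least k")
})

test_that("the mistake-minimizing tree separates 1-D point masses", {
  X <- matrix(c(rep(0, 20), rep(10, 20), rep(20, 20)) +
                rnorm(60, 0, 0.01), ncol = 1)
  km <- kmeans_cluster(X, 3, seed = 2)
  tree <- fit_mistake_minimizing_tree(X, km$labels, 3)
  expect_identical(myograph:::count_internal_nodes(tree$root), 2L)
  expect_identical(unname(predict(tree, X)), unname(km$labels))
  # thresholds fall strictly between the masses
  thr <- c(tree$root$threshold,
           if (!tree$root$left$leaf) tree$root$left$threshold else
             tree$root$right$threshold)
  expect_true(all(thr > 0.2 & thr < 19.8))
  expect_true(all(abs(thr - 10) > 2))
})

test_that("tree fidelity to k-means is high on separated Gaussians", {
  set.seed(44)
  n <- 100
  X <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 10), rnorm(n, 0)),
             cbind(rnorm(n, 5), rnorm(n, 10)))
  km <- kmeans_cluster(X, 3, seed = 6)
  tree <- fit_mistake_minimizing_tree(X, km$labels, 3)
  expect_identical(myograph:::count_internal_nodes(tree$root), 2L)
  expect_gte(mean(predict(tree, X) == km$labels), 0.95)
})

test_that("the root split equals an exhaustive nested-loop oracle", {
  set.seed(13)
  X <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  km <- kmeans_cluster(X, 3, seed = 3)
  tree <- fit_mistake_minimizing_tree(X, km$labels, 3)
  # independent oracle: loop every feature and midpoint, recompute the
  # mistake count from scratch
  best <- NULL
  for (f in 1:2) {
    u <- sort(unique(X[, f]))
    for (t in (u[-1] + u[-length(u)]) / 2) {
      mist <- 0; sides <- integer(3)
      for (cl in 1:3) {
        nl <- sum(X[km$labels == cl, f] <= t)
        nr <- sum(km$labels == cl) - nl
        sides[cl] <- if (nl >= nr) 1L else 2L
        mist <- mist + min(nl, nr)
      }
      if (length(unique(sides)) < 2) next
      if (is.null(best) || mist < best$mist)
        best <- list(f = f, t = t, mist = mist)
    }
  }
  expect_identical(tree$root$feature, best$f)
  expect_equal(tree$root$threshold, best$t)
  expect_equal(tree$root$mistakes, best$mist, ignore_attr = TRUE)
})

test_that("organization labels order by density and honor the zero rule", {
  co <- make_cohort(300, seed = 21)
  cl <- fit_organization_clusters(co$X, k = 3, seed = 2)
  n_sarc <- round(co$density * 1e4)
  labels <- assign_organization_labels(cl, co$X, n_sarc)
  expect_identical(levels(labels), c("Low", "Medium", "High"))
  # zero-sarcomere cells are Low regardless of their other features
  forced <- assign_organization_labels(cl, co$X, rep(0, nrow(co$X)))
  expect_true(all(forced == "Low"))
  # mean density strictly increases across Low -> Medium -> High
  dens_by <- tapply(co$density, labels, mean)
  expect_true(all(diff(dens_by[c("Low", "Medium", "High")]) > 0))
  # the densest training cluster maps to High
  km_lab <- cl$kmeans$labels
  dens_cl <- tapply(co$X[, "sarcomere_density"], km_lab, mean)
  expect_identical(unname(cl$label_map[names(which.max(dens_cl))]), "High")
})

test_that("agreement metrics match their textbook definitions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(evaluate_agreement(x, x), list(pearson = 1, agreement = 1))
  expect_equal(evaluate_agreement(x, rev(x))$pearson, -1)
  set.seed(17)
  for (rep in 1:10) {
    a <- runif(30, 1, 5); b <- runif(30, 1, 5)
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(evaluate_agreement(a, b)$pearson, r_oracle,
                 tolerance = 1e-12)
  }
  expect_error(evaluate_agreement(rep(1, 5), 1:5), "zero-variance")
  expect_error(evaluate_agreement(1:3, 1:4), "equal length")
})
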