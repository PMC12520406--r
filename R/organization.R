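# Organization-scoring heads: a supervised RBF-kernel support-vector
# regression against combined expert scores, and an unsupervised k-means
# plus mistake-minimizing threshold tree giving Low/Medium/High labels.

standardizer_fit <- function(X) {
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  keep <- scl > 1e-12
  if (!all(keep))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  list(center = ctr[keep], scale = scl[keep], keep = colnames(X)[keep])
}

standardizer_apply <- function(std, X) {
  scale(X[, std$keep, drop = FALSE], std$center, std$scale)
}

standardizer_invert <- function(std, Xs) {
  sweep(sweep(Xs, 2, std$scale, `*`), 2, std$center, `+`)
}

#' Train the supervised organization-score regressor
#'
#' Support-vector regression (RBF kernel; `C = 10`, `gamma = 0.1`,
#' `epsilon = 0.5`, via \pkg{e1071}) of the combined expert score
#' (`expert1 + expert2 - 1`, range 1..9) on standardized normalized
#' feature vectors. Standardization parameters are stored with the model.
#'
#' @param features numeric matrix (cells x 8 normalized features; see
#'   [normalize_features()]).
#' @param expert1,expert2 integer expert scores in 1..5.
#' @param combined optional precomputed combined target (overrides the
#'   expert columns).
#' @return A `sarc_svr` object; predict with [predict_scores()] or
#'   [predict()].
#' @export
train_score_regressor <- function(features, expert1 = NULL, expert2 = NULL,
                                  combined = NULL) {
  features <- as.matrix(features)
  if (is.null(combined)) {
    if (is.null(expert1) || is.null(expert2))
      stop("supply either both expert score vectors or `combined`",
           call. = FALSE)
    combined <- expert1 + expert2 - 1
  }
  if (nrow(features) < 10)
    stop("need at least 10 training samples", call. = FALSE)
  if (nrow(features) != length(combined))
    stop("feature and target lengths differ", call. = FALSE)
  std <- standardizer_fit(features)
  Xs <- standardizer_apply(std, features)
  fit <- e1071::svm(x = Xs, y = combined, type = "eps-regression",
                    kernel = "radial", cost = 10, gamma = 0.1,
                    epsilon = 0.5, scale = FALSE)
  structure(list(model = fit, standardizer = std), class = "sarc_svr")
}

#' Rescale a combined-score prediction to the 1-5 expert scale
#'
#' The combined target is `expert1 + expert2 - 1` (range 1..9); the
#' inverse map back to a single expert's scale is `(y + 1) / 2`, clipped
#' to [1, 5].
#'
#' @param y numeric vector on the combined 1..9 scale.
#' @return Numeric vector on the 1..5 scale.
#' @export
rescale_combined_score <- function(y) clamp((y + 1) / 2, 1, 5)

#' Predict organization scores on the 1-5 expert scale
#'
#' The raw SVR prediction (combined-score scale, 1..9) is mapped back to
#' the expert scale by `(y + 1) / 2` and clipped to [1, 5].
#'
#' @param regressor a `sarc_svr` from [train_score_regressor()].
#' @param features numeric matrix of normalized feature vectors.
#' @return Numeric vector of predicted scores in [1, 5]; the raw
#'   combined-scale predictions are attached as attribute `"raw"`.
#' @export
predict_scores <- function(regressor, features) {
  if (!inherits(regressor, "sarc_svr"))
    stop("`regressor` must be a fitted sarc_svr", call. = FALSE)
  Xs <- standardizer_apply(regressor$standardizer, as.matrix(features))
  raw <- as.numeric(predict(regressor$model, Xs))
  out <- rescale_combined_score(raw)
  attr(out, "raw") <- raw
  out
}

#' @export
predict.sarc_svr <- function(object, newdata, ...) predict_scores(object, newdata)

#' @export
print.sarc_svr <- function(x, ...) {
  cat("Organization-score SVR (RBF kernel, C = 10, gamma = 0.1, epsilon = 0.5)\n")
  cat("  features: ", paste(x$standardizer$keep, collapse = ", "), "\n",
      sep = "")
  cat("  support vectors: ", x$model$tot.nSV, "\n", sep = "")
  invisible(x)
}

#' Seeded k-means clustering
#'
#' Lloyd-style k-means (via [stats::kmeans()]) with a seeded multi-start.
#'
#' @param features numeric matrix.
#' @param k cluster count.
#' @param seed integer seed.
#' @param nstart random restarts.
#' @return List with `labels` (integers 1..k), `centers`, and `tot_withinss`.
#' @export
kmeans_cluster <- function(features, k = 3, seed = 1, nstart = 10) {
  features <- as.matrix(features)
  if (nrow(features) < k)
    stop("need at least k samples to form k clusters", call. = FALSE)
  set.seed(seed)
  km <- kmeans(features, centers = k, nstart = nstart, iter.max = 100)
  list(labels = km$cluster, centers = km$centers,
       tot_withinss = km$tot.withinss)
}

# --- mistake-minimizing threshold tree -------------------------------------

# Best axis-aligned split of the samples in `idx` over clusters `cl_set`:
# candidate thresholds are midpoints between consecutive sorted unique
# feature values; each cluster is assigned to the side holding the
# majority of its samples, and the cost is the number of samples on their
# cluster's minority side. Splits must separate the clusters into two
# non-empty groups.
best_split <- function(X, labels, idx, cl_set) {
  best <- NULL
  for (f in seq_len(ncol(X))) {
    u <- sort(unique(X[idx, f]))
    if (length(u) < 2) next
    cuts <- (u[-1] + u[-length(u)]) / 2
    for (t in cuts) {
      left <- X[idx, f] <= t
      mistakes <- 0L
      side_of <- integer(length(cl_set))
      ok <- TRUE
      for (ci in seq_along(cl_set)) {
        in_c <- labels[idx] == cl_set[ci]
        nl <- sum(left & in_c); nr <- sum(!left & in_c)
        side_of[ci] <- if (nl >= nr) 1L else 2L
        mistakes <- mistakes + min(nl, nr)
      }
      if (length(unique(side_of)) < 2) ok <- FALSE
      if (ok && (is.null(best) || mistakes < best$mistakes)) {
        best <- list(feature = f, threshold = t, mistakes = mistakes,
                     left_clusters = cl_set[side_of == 1L],
                     right_clusters = cl_set[side_of == 2L])
      }
    }
  }
  best
}

build_imm_node <- function(X, labels, idx, cl_set) {
  if (length(cl_set) == 1)
    return(list(leaf = TRUE, cluster = cl_set))
  sp <- best_split(X, labels, idx, cl_set)
  if (is.null(sp)) {
    # degenerate: identical points across clusters; pick the majority
    maj <- cl_set[which.max(tabulate(match(labels[idx], cl_set)))]
    return(list(leaf = TRUE, cluster = maj))
  }
  go_left <- X[idx, sp$feature] <= sp$threshold
  in_left_cl <- labels[idx] %in% sp$left_clusters
  # IMM routing: mistaken samples (wrong side of their cluster's majority)
  # are dropped from deeper splits
  left_idx <- idx[go_left & in_left_cl]
  right_idx <- idx[!go_left & !in_left_cl]
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       mistakes = sp$mistakes,
       left = build_imm_node(X, labels, left_idx, sp$left_clusters),
       right = build_imm_node(X, labels, right_idx, sp$right_clusters))
}

#' Fit a mistake-minimizing threshold tree to k-means clusters
#'
#' Greedy explainable-clustering tree: each internal node picks the
#' axis-aligned split (feature, threshold at a midpoint between
#' consecutive unique values) minimizing the number of samples separated
#' from their cluster's majority side, recursing until each leaf holds one
#' cluster. For k clusters the tree has exactly k - 1 internal splits.
#'
#' @param features numeric matrix.
#' @param labels integer cluster labels (e.g. from [kmeans_cluster()]).
#' @param k cluster count (defaults to the number of distinct labels).
#' @return A `threshold_tree` object; predict with [predict()].
#' @export
fit_mistake_minimizing_tree <- function(features, labels,
                                        k = length(unique(labels))) {
  features <- as.matrix(features)
  cl_set <- sort(unique(labels))
  if (length(cl_set) != k)
    stop("`labels` must contain exactly k distinct clusters", call. = FALSE)
  root <- build_imm_node(features, labels, seq_len(nrow(features)), cl_set)
  structure(list(root = root, n_features = ncol(features),
                 feature_names = colnames(features)),
            class = "threshold_tree")
}

tree_route <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$cluster
}

#' @export
predict.threshold_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  apply(newdata, 1, function(x) tree_route(object$root, x))
}

count_internal_nodes <- function(node) {
  if (node$leaf) return(0L)
  1L + count_internal_nodes(node$left) + count_internal_nodes(node$right)
}

#' @export
print.threshold_tree <- function(x, ...) {
  cat("Mistake-minimizing threshold tree: ", count_internal_nodes(x$root),
      " internal split(s)\n", sep = "")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, "leaf -> cluster ", node$cluster, "\n", sep = "")
    } else {
      nm <- if (!is.null(x$feature_names)) x$feature_names[node$feature] else
        paste0("feature ", node$feature)
      cat(pad, nm, " <= ", signif(node$threshold, 5), " (",
          node$mistakes, " mistakes)\n", sep = "")
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(x$root, 1)
  invisible(x)
}

#' Unsupervised organization clustering head
#'
#' Clusters cells into k groups by seeded k-means on the normalized
#' feature vectors, fits a mistake-minimizing threshold tree to make the
#' clusters explainable, and orders clusters into organization labels
#' (Low < Medium < High for k = 3) by ascending mean sarcomere density of
#' the training clusters.
#'
#' @param features numeric matrix of normalized feature vectors; must
#'   contain a `sarcomere_density` column (see [normalize_features()]).
#' @param k number of organization groups (default 3).
#' @param seed seed for k-means.
#' @return A `sarc_clusters` object; label new cells with
#'   [assign_organization_labels()].
#' @export
fit_organization_clusters <- function(features, k = 3, seed = 1) {
  features <- as.matrix(features)
  if (!"sarcomere_density" %in% colnames(features))
    stop("`features` must contain a `sarcomere_density` column", call. = FALSE)
  km <- kmeans_cluster(features, k = k, seed = seed)
  tree <- fit_mistake_minimizing_tree(features, km$labels, k = k)
  dens <- tapply(features[, "sarcomere_density"], km$labels, mean)
  ord <- order(dens)   # ascending density -> Low .. High
  level_names <- if (k == 3) c("Low", "Medium", "High") else
    paste0("G", seq_len(k))
  label_map <- setNames(level_names[order(ord)], names(dens))
  structure(list(kmeans = km, tree = tree, label_map = label_map,
                 levels = level_names),
            class = "sarc_clusters")
}

#' @export
print.sarc_clusters <- function(x, ...) {
  cat("Unsupervised organization clustering (k-means + threshold tree)\n")
  cat("  cluster -> label: ",
      paste(names(x$label_map), x$label_map, sep = "=", collapse = ", "),
      "\n", sep = "")
  print(x$tree)
  invisible(x)
}

#' Assign Low/Medium/High organization labels
#'
#' Cells with zero detected sarcomeres are labeled Low outright; all
#' others are routed through the threshold tree and mapped to the
#' density-ordered labels.
#'
#' @param clusters a `sarc_clusters` from [fit_organization_clusters()].
#' @param features numeric matrix of normalized feature vectors.
#' @param n_sarcomeres per-cell sarcomere counts (same order as rows of
#'   `features`).
#' @return Factor with levels Low, Medium, High (in that order).
#' @export
assign_organization_labels <- function(clusters, features, n_sarcomeres) {
  features <- as.matrix(features)
  if (nrow(features) != length(n_sarcomeres))
    stop("`n_sarcomeres` must match the rows of `features`", call. = FALSE)
  cl <- predict(clusters$tree, features)
  lab <- unname(clusters$label_map[as.character(cl)])
  lab[n_sarcomeres == 0] <- "Low"
  factor(lab, levels = clusters$levels)
}

#' Agreement between two score vectors
#'
#' Pearson correlation plus the exact-agreement rate after rounding the
#' predictions to the nearest integer in 1..5 (half-up).
#'
#' @param pred,target numeric vectors of equal length (>= 2).
#' @return List with `pearson` and `agreement`.
#' @export
evaluate_agreement <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 2)
    stop("`pred` and `target` must have equal length >= 2", call. = FALSE)
  if (sd(pred) == 0 || sd(target) == 0)
    stop("correlation undefined for zero-variance input", call. = FALSE)
  list(pearson = cor(pred, target),
       agreement = mean(clamp(round_half_up(pred), 1, 5) ==
                          clamp(round_half_up(target), 1, 5)))
}
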