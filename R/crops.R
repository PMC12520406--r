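# Contour-centered crops and the pluggable z-disc classifier pair.
#
# Every detected contour is represented by a 128 x 128 crop centered on its
# centroid, expanded into two 3-channel input types:
#   Type 1 (intensity preserving): raw crop; raw masked to the target
#     contour interior; raw masked to the union of all other interiors.
#   Type 2 (intensity invariant): LoG-filtered crop; binary fill of the
#     target contour; binary fill of all other contours.

# Rasterize all contour interiors once: returns a list of 0-based pixel
# coordinate matrices and a global occupancy count matrix.
rasterize_contours <- function(contours, nr, nc) {
  occupancy <- matrix(0L, nr, nc)
  interiors <- vector("list", length(contours))
  for (i in seq_along(contours)) {
    px <- contour_interior_pixels(contours[[i]], nr, nc)
    interiors[[i]] <- px
    if (nrow(px)) {
      idx <- cbind(px[, 1] + 1, px[, 2] + 1)
      occupancy[idx] <- occupancy[idx] + 1L
    }
  }
  list(interiors = interiors, occupancy = occupancy)
}

crop_window <- function(x, center_rc, size) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, size, size)
  r0 <- round(center_rc[1]) - size %/% 2   # 0-based start
  c0 <- round(center_rc[2]) - size %/% 2
  rs <- max(0, r0):min(nr - 1, r0 + size - 1)
  cs <- max(0, c0):min(nc - 1, c0 + size - 1)
  if (length(rs) && length(cs) && rs[1] <= rs[length(rs)])
    out[rs - r0 + 1, cs - c0 + 1] <- x[rs + 1, cs + 1]
  out
}

#' Build a 3-channel contour crop (both input types)
#'
#' Crops a `size` x `size` region of the image centered on the target
#' contour's centroid (zero-padded at image borders) and assembles the
#' Type 1 (pixel-intensity preserving) and Type 2 (pixel-intensity
#' invariant) channel stacks used by the z-disc classifiers.
#'
#' @param image numeric matrix (raw intensities).
#' @param contours list of contours from [extract_contours()].
#' @param target_index index of the contour this crop represents.
#' @param filtered optional precomputed LoG-filtered image (computed with
#'   `log_filter(image, 1)` when missing).
#' @param size crop side length (128 px by default).
#' @param raster optional precomputed [rasterize_contours()] result, to
#'   avoid re-rasterizing when building many crops of one image.
#' @return A `contour_crop` object: list with `contour_id`, `centroid`,
#'   `type1` and `type2` (size x size x 3 arrays), `target_mask` (logical),
#'   `perimeter`, `area`, and `vertices` of the target contour.
#' @export
build_crop <- function(image, contours, target_index, filtered = NULL,
                       size = 128, raster = NULL) {
  stop_if_not_image(image)
  if (target_index < 1 || target_index > length(contours))
    stop("`target_index` out of range", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(filtered)) filtered <- log_filter(image, 1)
  if (is.null(raster)) raster <- rasterize_contours(contours, nr, nc)
  target <- matrix(0L, nr, nc)
  px <- raster$interiors[[target_index]]
  if (nrow(px)) target[cbind(px[, 1] + 1, px[, 2] + 1)] <- 1L
  others <- (raster$occupancy - target) > 0
  ct <- contours[[target_index]]
  ctr <- ct$centroid

  raw_c <- crop_window(image, ctr, size)
  filt_c <- crop_window(filtered, ctr, size)
  tgt_c <- crop_window(target, ctr, size)
  oth_c <- crop_window(others * 1L, ctr, size)

  type1 <- array(c(raw_c, raw_c * tgt_c, raw_c * oth_c), c(size, size, 3))
  type2 <- array(c(filt_c, tgt_c, oth_c), c(size, size, 3))
  structure(list(
    contour_id = ct$id, centroid = ctr,
    type1 = type1, type2 = type2,
    target_mask = tgt_c > 0,
    perimeter = ct$perimeter, area = ct$area, vertices = ct$vertices
  ), class = "contour_crop")
}

#' Build crops for all contours of one image
#'
#' @inheritParams build_crop
#' @param indices contour indices to crop (all by default).
#' @return List of `contour_crop` objects.
#' @export
build_crops <- function(image, contours, filtered = NULL, size = 128,
                        indices = seq_along(contours)) {
  if (is.null(filtered)) filtered <- log_filter(image, 1)
  raster <- rasterize_contours(contours, nrow(image), ncol(image))
  lapply(indices, function(i)
    build_crop(image, contours, i, filtered = filtered, size = size,
               raster = raster))
}

# --- hand-crafted crop descriptors -----------------------------------------

# Second-moment shape of a weighted point cloud: returns eccentricity and
# aspect ratio (sqrt of eigenvalue ratio).
weighted_shape <- function(rows, cols, w) {
  sw <- sum(w)
  if (sw <= 0 || length(rows) < 2) return(c(ecc = 0, aspect = 1))
  mr <- sum(w * rows) / sw; mc <- sum(w * cols) / sw
  vrr <- sum(w * (rows - mr)^2) / sw
  vcc <- sum(w * (cols - mc)^2) / sw
  vrc <- sum(w * (rows - mr) * (cols - mc)) / sw
  tr <- vrr + vcc
  det <- vrr * vcc - vrc^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  c(ecc = sqrt(max(0, 1 - l2 / l1)), aspect = sqrt(l1 / l2))
}

# Type 1: intensity statistics inside vs outside the target contour, plus
# the intensity-weighted second-moment shape of the masked signal.
crop_descriptors_type1 <- function(crop) {
  raw <- crop$type1[, , 1]
  inside <- crop$target_mask
  vi <- raw[inside]; vo <- raw[!inside]
  if (length(vi) == 0) vi <- 0
  mi <- mean(vi); mo <- mean(vo)
  idx <- which(inside, arr.ind = TRUE)
  shp <- if (nrow(idx) >= 2)
    weighted_shape(idx[, 1], idx[, 2], raw[inside]) else c(ecc = 0, aspect = 1)
  c(n_inside = log1p(sum(inside)),
    mean_in = mi, sd_in = if (length(vi) > 1) sd(vi) else 0,
    max_in = max(vi),
    mean_out = mo, sd_out = if (length(vo) > 1) sd(vo) else 0,
    contrast = (mi - mo) / (mi + mo + 1e-12),
    w_ecc = unname(shp["ecc"]), w_aspect = unname(shp["aspect"]))
}

# Type 2: shape descriptors of the target contour polygon / binary mask.
crop_descriptors_type2 <- function(crop) {
  v <- crop$vertices
  hull <- grDevices::chull(v[, 2], v[, 1])
  hull_area <- polygon_area(v[hull, , drop = FALSE])
  idx <- which(crop$target_mask, arr.ind = TRUE)
  shp <- if (nrow(idx) >= 2)
    weighted_shape(idx[, 1], idx[, 2], rep(1, nrow(idx))) else
      c(ecc = 0, aspect = 1)
  p <- crop$perimeter; a <- crop$area
  c(perimeter = p, area = a,
    eccentricity = unname(shp["ecc"]), aspect = unname(shp["aspect"]),
    solidity = if (hull_area > 0) a / hull_area else 1,
    compactness = if (p > 0) 4 * pi * a / p^2 else 0)
}

crop_descriptors <- function(crops, input_type) {
  fn <- if (input_type == 1) crop_descriptors_type1 else crop_descriptors_type2
  t(vapply(crops, fn, fn(crops[[1]])))
}

# --- baseline classifier ----------------------------------------------------

#' Train the baseline z-disc crop classifier
#'
#' A ridge-regularized logistic model (via \pkg{glmnet}) over hand-crafted
#' crop descriptors: intensity statistics inside vs outside the target
#' contour for input type 1, and contour shape descriptors (perimeter,
#' area, eccentricity, solidity, aspect ratio, compactness) for input
#' type 2. This is a lightweight, fully reproducible stand-in satisfying
#' the classifier contract; any user model producing a probability in
#' [0, 1] per crop is pluggable in its place.
#'
#' @param crops list of `contour_crop` objects.
#' @param labels factor or character with levels `zdisc` / `not_zdisc`.
#' @param input_type 1 or 2 (which channel stack the classifier reads).
#' @param holdout_frac fraction of crops held out to report accuracy.
#' @param seed seed for the train/holdout split.
#' @param lambda ridge penalty.
#' @return A `zdisc_classifier` object with a [predict()] method returning
#'   probabilities in [0, 1]; `$holdout_accuracy` reports held-out accuracy.
#' @export
train_baseline_classifier <- function(crops, labels, input_type = 2,
                                      holdout_frac = 0.25, seed = 1,
                                      lambda = 0.01) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  if (min(table(labels)) < 2)
    stop("need at least 2 examples per class", call. = FALSE)
  if (!input_type %in% c(1, 2)) stop("`input_type` must be 1 or 2", call. = FALSE)
  X <- crop_descriptors(crops, input_type)
  y <- as.integer(labels == "zdisc")
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  keep <- scl > 1e-10
  if (!all(keep))
    warning("dropping zero-variance descriptor(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  Xs <- scale(X[, keep, drop = FALSE], ctr[keep], scl[keep])

  set.seed(seed)
  n <- nrow(Xs)
  n_test <- max(1L, round(holdout_frac * n))
  test_idx <- sample(n, n_test)
  fit <- glmnet::glmnet(Xs[-test_idx, , drop = FALSE], y[-test_idx],
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  b <- as.numeric(stats::coef(fit))
  obj <- structure(list(
    input_type = input_type,
    descriptors = colnames(X)[keep],
    center = ctr[keep], scale = scl[keep],
    intercept = b[1], beta = b[-1],
    lambda = lambda
  ), class = "zdisc_classifier")
  pred <- predict(obj, crops[test_idx])
  obj$holdout_accuracy <- mean((pred >= 0.5) == (y[test_idx] == 1))
  obj
}

#' @export
predict.zdisc_classifier <- function(object, crops, ...) {
  X <- crop_descriptors(crops, object$input_type)
  X <- X[, object$descriptors, drop = FALSE]
  Xs <- scale(X, object$center, object$scale)
  as.numeric(stats::plogis(object$intercept + Xs %*% object$beta))
}

#' @export
print.zdisc_classifier <- function(x, ...) {
  cat("Baseline z-disc crop classifier (input type ", x$input_type, ")\n",
      sep = "")
  cat("  descriptors: ", paste(x$descriptors, collapse = ", "), "\n", sep = "")
  if (!is.null(x$holdout_accuracy))
    cat(sprintf("  held-out accuracy: %.3f\n", x$holdout_accuracy))
  invisible(x)
}

#' Ground-truth oracle classifier
#'
#' A classifier-contract implementation driven by synthetic ground truth:
#' a crop scores `p_hit` when its contour centroid lies within
#' `match_radius` of a true z-disc center and `p_miss` otherwise. Used to
#' benchmark the downstream pipeline independently of classifier quality.
#'
#' @param ground_truth the `ground_truth` element of a [generate_cell()]
#'   result.
#' @param match_radius matching radius in pixels.
#' @param p_hit,p_miss probabilities returned for matched / unmatched
#'   crops.
#' @param input_type nominal input type (1 or 2); the oracle reads only
#'   the crop centroid.
#' @return A `zdisc_classifier_oracle` object with a [predict()] method.
#' @export
oracle_classifier <- function(ground_truth, match_radius = 3,
                              p_hit = 0.99, p_miss = 0.01, input_type = 1) {
  structure(list(centers = ground_truth$centers,
                 is_zdisc = ground_truth$is_zdisc,
                 match_radius = match_radius,
                 p_hit = p_hit, p_miss = p_miss,
                 input_type = input_type),
            class = "zdisc_classifier_oracle")
}

#' @export
predict.zdisc_classifier_oracle <- function(object, crops, ...) {
  ctr <- object$centers[object$is_zdisc, , drop = FALSE]
  vapply(crops, function(crop) {
    if (nrow(ctr) == 0) return(object$p_miss)
    d <- sqrt((ctr[, 1] - crop$centroid[1])^2 +
                (ctr[, 2] - crop$centroid[2])^2)
    if (min(d) <= object$match_radius) object$p_hit else object$p_miss
  }, numeric(1))
}

#' Score contour crops with a classifier pair
#'
#' Applies the two classifiers (one per input type) to every crop and
#' averages their probabilities into the final z-disc probability.
#'
#' @param crops list of `contour_crop` objects.
#' @param classifier1,classifier2 objects with a [predict()] method
#'   mapping crops to probabilities in [0, 1].
#' @return data.frame with columns `contour_id`, `p1`, `p2`, `p_zdisc`.
#' @export
classify_candidates <- function(crops, classifier1, classifier2) {
  if (length(crops) == 0)
    return(data.frame(contour_id = integer(0), p1 = numeric(0),
                      p2 = numeric(0), p_zdisc = numeric(0)))
  p1 <- predict(classifier1, crops)
  p2 <- predict(classifier2, crops)
  for (p in list(p1, p2)) {
    if (!all(is.finite(p)) || any(p < 0) || any(p > 1))
      stop("classifier output violates the [0, 1] probability contract",
           call. = FALSE)
  }
  data.frame(contour_id = vapply(crops, `[[`, integer(1), "contour_id"),
             p1 = p1, p2 = p2, p_zdisc = (p1 + p2) / 2)
}

#' Filter candidates by z-disc probability
#'
#' Keeps candidates with `p_zdisc >= threshold`. The default threshold of
#' 0.3 removes contours the classifier pair considers very unlikely to be
#' z-discs while retaining uncertain ones for graph-level evidence.
#'
#' @param candidates data.frame from [classify_candidates()].
#' @param threshold probability cutoff in [0, 1].
#' @return Filtered data.frame.
#' @export
filter_by_probability <- function(candidates, threshold = 0.3) {
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  candidates[candidates$p_zdisc >= threshold, , drop = FALSE]
}

#' Save / load a baseline classifier as JSON
#'
#' @param classifier a `zdisc_classifier`.
#' @param path JSON path.
#' @export
save_classifier <- function(classifier, path) {
  if (!inherits(classifier, "zdisc_classifier"))
    stop("only baseline `zdisc_classifier` objects are serializable",
         call. = FALSE)
  obj <- unclass(classifier)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  obj$center <- setNames(as.numeric(obj$center), obj$descriptors)
  obj$scale <- setNames(as.numeric(obj$scale), obj$descriptors)
  obj$beta <- as.numeric(obj$beta)
  structure(obj, class = "zdisc_classifier")
}
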