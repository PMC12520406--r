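# Per-cell structural features derived from the detection result.

#' Nematic orientational order parameter
#'
#' The 2-D nematic order parameter
#' `OOP = sqrt(mean(cos 2 theta)^2 + mean(sin 2 theta)^2)`
#' (equivalently twice the leading eigenvalue of the mean orientation
#' tensor minus one): 1 for perfectly aligned orientations, 0 for an
#' isotropic set. Invariant under global rotation and under
#' `theta -> theta + pi`.
#'
#' @param orientations numeric vector of orientations in radians.
#' @return Value in [0, 1]; an empty input returns 0 with a warning.
#' @export
orientation_order_parameter <- function(orientations) {
  if (length(orientations) == 0) {
    warning("no orientations supplied; OOP defined as 0")
    return(0)
  }
  sqrt(mean(cos(2 * orientations))^2 + mean(sin(2 * orientations))^2)
}

#' Per-cell structural features
#'
#' Computes the nine-feature structural descriptor of a cell from a
#' detection result: average and SD of sarcomere length (sample SD, 0 for
#' fewer than two sarcomeres), the orientational order parameter of the
#' final sarcomeres, cell area, sarcomere and myofibril counts, average
#' sarcomeres per myofibril, the fraction of detected contours classified
#' as z-discs (probability > 0.5, over all contours surviving the length
#' filter), and the probabilistic z-disc area (sum of contour area times
#' z-disc probability). A cell with no sarcomeres gets zeros for the
#' length/orientation/count features, so downstream labeling remains
#' defined.
#'
#' @param detection a `sarc_detection` from [detect_sarcomeres()].
#' @param cell_area cell area in px^2; defaults to the mask area if a
#'   mask was supplied, otherwise the full image area.
#' @return A `cell_features` object (named list of the nine features).
#' @export
cell_features <- function(detection, cell_area = NULL) {
  if (!inherits(detection, "sarc_detection"))
    stop("`detection` must be a sarc_detection", call. = FALSE)
  if (is.null(cell_area)) cell_area <- detection$cell_area
  if (cell_area <= 0) stop("`cell_area` must be > 0", call. = FALSE)

  sarc <- final_sarcomeres(detection)
  n_sarc <- nrow(sarc)
  n_myo <- length(detection$myofibrils)
  cand <- detection$candidates
  feats <- list(
    avg_sarcomere_length = if (n_sarc) mean(sarc$length) else 0,
    sd_sarcomere_length = if (n_sarc > 1) sd(sarc$length) else 0,
    orientation_order_parameter = if (n_sarc)
      orientation_order_parameter(sarc$orientation) else 0,
    cell_area = cell_area,
    n_sarcomeres = n_sarc,
    n_myofibrils = n_myo,
    avg_sarcomeres_per_myofibril = if (n_myo) n_sarc / n_myo else 0,
    zdisc_classification_ratio = if (nrow(cand))
      mean(cand$p_zdisc > 0.5) else 0,
    probabilistic_zdisc_area = if (nrow(cand))
      sum(cand$area * cand$p_zdisc) else 0
  )
  structure(feats, class = "cell_features")
}

#' @export
print.cell_features <- function(x, ...) {
  cat("Cell structural features:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Model-ready normalized feature vector
#'
#' Returns the 8-element vector used by the organization models: average
#' and SD sarcomere length, OOP, sarcomere density and myofibril density
#' (counts per px^2 of cell area), sarcomeres per myofibril, z-disc
#' classification ratio, and probabilistic z-disc area fraction. Cell
#' area itself is not a direct feature; it only normalizes the three
#' area-dependent entries.
#'
#' @param features a [cell_features()] object (or a list/row with the
#'   nine feature names).
#' @return Named numeric vector of length 8.
#' @export
normalize_features <- function(features) {
  a <- features$cell_area
  if (is.null(a) || a <= 0) stop("cell_area must be > 0", call. = FALSE)
  c(avg_sarcomere_length = features$avg_sarcomere_length,
    sd_sarcomere_length = features$sd_sarcomere_length,
    orientation_order_parameter = features$orientation_order_parameter,
    sarcomere_density = features$n_sarcomeres / a,
    myofibril_density = features$n_myofibrils / a,
    avg_sarcomeres_per_myofibril = features$avg_sarcomeres_per_myofibril,
    zdisc_classification_ratio = features$zdisc_classification_ratio,
    prob_zdisc_area_fraction = features$probabilistic_zdisc_area / a)
}

#' Feature table for a set of cells
#'
#' Binds raw and normalized features of several cells into one
#' data.frame, one row per cell.
#'
#' @param feature_list list of [cell_features()] objects.
#' @param cell_ids optional identifiers (default sequential).
#' @return data.frame with `cell_id`, the nine raw features, and the
#'   eight normalized columns (prefixed `norm_`).
#' @export
feature_table <- function(feature_list, cell_ids = seq_along(feature_list)) {
  rows <- lapply(seq_along(feature_list), function(i) {
    f <- feature_list[[i]]
    nv <- normalize_features(f)
    cbind(data.frame(cell_id = cell_ids[i]),
          as.data.frame(f[names(f)]),
          setNames(as.data.frame(as.list(nv)), paste0("norm_", names(nv))))
  })
  do.call(rbind, rows)
}
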