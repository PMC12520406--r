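# Sub-pixel z-disc localization: contour centroids are replaced by local
# intensity peaks of a smoothed, continuously interpolable image surface.

#' Smooth, continuously evaluable intensity surface
#'
#' Gaussian-smooths the image (via `EBImage::gblur`; `sigma_smooth = 0`
#' skips smoothing) and wraps it in a bicubic (Catmull-Rom) interpolant
#' evaluable at sub-pixel coordinates. The interpolant reproduces pixel
#' values exactly at integer coordinates.
#'
#' @param image numeric matrix.
#' @param sigma_smooth Gaussian smoothing sigma in pixels (>= 0).
#' @return An `intensity_surface` object; evaluate with [surface_eval()].
#' @export
smooth_surface <- function(image, sigma_smooth = 1) {
  stop_if_not_image(image)
  if (sigma_smooth < 0) stop("`sigma_smooth` must be >= 0", call. = FALSE)
  sm <- if (sigma_smooth > 0) {
    matrix(as.numeric(EBImage::gblur(image, sigma = sigma_smooth,
                                     boundary = "replicate")),
           nrow(image), ncol(image))
  } else image
  structure(list(values = sm, nr = nrow(image), nc = ncol(image),
                 sigma_smooth = sigma_smooth),
            class = "intensity_surface")
}

# Keys cubic convolution kernel weights (a = -1/2, Catmull-Rom) for
# fractional offset t in [0, 1): weights for samples at -1, 0, 1, 2.
cubic_weights <- function(t) {
  cbind(((-t + 2) * t - 1) * t / 2,
        ((3 * t - 5) * t * t + 2) / 2,
        ((-3 * t + 4) * t + 1) * t / 2,
        (t - 1) * t * t / 2)
}

#' Evaluate an intensity surface at sub-pixel coordinates
#'
#' @param surface an [smooth_surface()] object.
#' @param rc numeric vector `c(row, col)` or an n x 2 matrix of 0-based
#'   coordinates.
#' @return Numeric vector of interpolated intensities.
#' @export
surface_eval <- function(surface, rc) {
  if (is.null(dim(rc))) rc <- matrix(rc, ncol = 2)
  V <- surface$values
  r <- clamp(rc[, 1], 0, surface$nr - 1)
  c_ <- clamp(rc[, 2], 0, surface$nc - 1)
  i0 <- floor(r); j0 <- floor(c_)
  tr <- r - i0; tc <- c_ - j0
  wr <- cubic_weights(tr); wc <- cubic_weights(tc)
  out <- numeric(nrow(rc))
  for (m in 1:4) {
    ri <- clamp(i0 + m - 2, 0, surface$nr - 1) + 1
    acc <- numeric(nrow(rc))
    for (n in 1:4) {
      cj <- clamp(j0 + n - 2, 0, surface$nc - 1) + 1
      acc <- acc + wc[, n] * V[cbind(ri, cj)]
    }
    out <- out + wr[, m] * acc
  }
  out
}

# TRUE for points whose surface value dominates a small probe cross
# around them (within the ascent bounds); rejects saddle points.
local_maximum_mask <- function(surface, pts, ints, lo, hi, h = 0.35) {
  n <- nrow(pts)
  ok <- rep(TRUE, n)
  for (d in list(c(h, 0), c(-h, 0), c(0, h), c(0, -h))) {
    probe <- cbind(clamp(pts[, 1] + d[1], lo[1], hi[1]),
                   clamp(pts[, 2] + d[2], lo[2], hi[2]))
    ok <- ok & (surface_eval(surface, probe) <= ints + 1e-9)
  }
  ok
}

# Bounded multi-start gradient ascent, vectorized over starts: central-
# difference gradients on the interpolated surface, per-start adaptive
# step with backtracking, positions clamped to [lo, hi].
ascend_surface <- function(surface, starts, lo, hi, max_iter = 200,
                           tol = 1e-6) {
  p <- starts
  n <- nrow(p)
  step <- rep(0.5, n)
  f <- surface_eval(surface, p)
  h <- 1e-3
  for (it in seq_len(max_iter)) {
    probe <- rbind(cbind(p[, 1] + h, p[, 2]), cbind(p[, 1] - h, p[, 2]),
                   cbind(p[, 1], p[, 2] + h), cbind(p[, 1], p[, 2] - h))
    fp <- surface_eval(surface, probe)
    g <- cbind(fp[1:n] - fp[(n + 1):(2 * n)],
               fp[(2 * n + 1):(3 * n)] - fp[(3 * n + 1):(4 * n)]) / (2 * h)
    gn <- sqrt(rowSums(g^2))
    active <- step > tol & gn > 1e-12
    if (!any(active)) break
    dirn <- g / pmax(gn, 1e-12)
    prop <- p + step * dirn
    prop[, 1] <- clamp(prop[, 1], lo[1], hi[1])
    prop[, 2] <- clamp(prop[, 2], lo[2], hi[2])
    fprop <- surface_eval(surface, prop)
    better <- active & (fprop > f)
    p[better, ] <- prop[better, , drop = FALSE]
    f[better] <- fprop[better]
    step[better] <- step[better] * 1.3
    step[active & !better] <- step[active & !better] * 0.5
  }
  p
}

#' Locate intensity peaks inside a contour
#'
#' Runs bounded gradient ascent (central-difference gradients with an
#' adaptive step, clamped to the dilated contour bounding box) from
#' `n_starts` points sampled uniformly inside the contour, merges
#' converged points closer than `merge_radius`, and returns the distinct
#' local maxima sorted by intensity (descending). The ascent is confined
#' to the contour's bounding box dilated by 2 px so peaks cannot escape to
#' neighboring structures.
#'
#' @param surface an [smooth_surface()] object.
#' @param contour a contour from [extract_contours()].
#' @param n_starts number of random starts (>= 1).
#' @param seed seed for the start sampling.
#' @param merge_radius radius (px) within which converged points count as
#'   one peak.
#' @return data.frame with columns `row`, `col`, `intensity`, sorted by
#'   decreasing intensity.
#' @export
find_peaks_in_contour <- function(surface, contour, n_starts = 10, seed = 1,
                                  merge_radius = 1.5) {
  if (n_starts < 1) stop("`n_starts` must be >= 1", call. = FALSE)
  px <- contour_interior_pixels(contour, surface$nr, surface$nc)
  if (nrow(px) == 0)
    stop("contour has no interior pixels", call. = FALSE)
  v <- contour$vertices
  lo <- c(max(0, min(v[, 1]) - 2), max(0, min(v[, 2]) - 2))
  hi <- c(min(surface$nr - 1, max(v[, 1]) + 2),
          min(surface$nc - 1, max(v[, 2]) + 2))
  set.seed(seed)
  starts <- px[sample(nrow(px), n_starts, replace = TRUE), , drop = FALSE] +
    matrix(runif(2 * n_starts, -0.4, 0.4), ncol = 2)
  starts[, 1] <- clamp(starts[, 1], lo[1], hi[1])
  starts[, 2] <- clamp(starts[, 2], lo[2], hi[2])

  pts <- ascend_surface(surface, starts, lo, hi)
  ints <- surface_eval(surface, pts)
  # discard converged points that are not local maxima (saddle points can
  # trap starts lying on their stable manifold)
  is_max <- local_maximum_mask(surface, pts, ints, lo, hi)
  if (any(is_max)) {
    pts <- pts[is_max, , drop = FALSE]
    ints <- ints[is_max]
  } else {
    best <- which.max(ints)
    pts <- pts[best, , drop = FALSE]
    ints <- ints[best]
  }
  ord <- order(-ints)
  peaks <- matrix(numeric(0), 0, 2); pint <- numeric(0)
  for (i in ord) {
    if (nrow(peaks) == 0 ||
        min(sqrt((peaks[, 1] - pts[i, 1])^2 +
                   (peaks[, 2] - pts[i, 2])^2)) > merge_radius) {
      peaks <- rbind(peaks, pts[i, ])
      pint <- c(pint, ints[i])
    }
  }
  data.frame(row = peaks[, 1], col = peaks[, 2], intensity = pint)
}

#' Convert contour peaks into z-discs
#'
#' The primary (strongest) peak becomes a z-disc carrying the candidate's
#' classifier probability. Each secondary peak whose intensity is at least
#' `ratio_threshold` of the primary intensity becomes an additional z-disc
#' whose probability is the contour probability multiplied by the
#' intensity ratio; weaker peaks are discarded. An empty peak list falls
#' back to the contour centroid with a warning.
#'
#' @param peaks data.frame from [find_peaks_in_contour()] (sorted by
#'   decreasing intensity).
#' @param candidate one-row data.frame (or list) with `p_zdisc` and
#'   `contour_id`.
#' @param contour the parent contour (used for the centroid fallback).
#' @param ratio_threshold secondary-to-primary intensity ratio cutoff,
#'   in (0, 1]; default 0.6.
#' @return data.frame with columns `row`, `col`, `p_zdisc`,
#'   `parent_contour_id`, `is_secondary`, `is_virtual`, `peak_intensity`.
#' @export
assign_zdiscs <- function(peaks, candidate, contour, ratio_threshold = 0.6) {
  if (ratio_threshold <= 0 || ratio_threshold > 1)
    stop("`ratio_threshold` must be in (0, 1]", call. = FALSE)
  p0 <- candidate$p_zdisc
  if (nrow(peaks) == 0) {
    warning("no peaks found in contour ", candidate$contour_id,
            "; falling back to the contour centroid")
    return(data.frame(row = unname(contour$centroid[1]),
                      col = unname(contour$centroid[2]),
                      p_zdisc = p0, parent_contour_id = candidate$contour_id,
                      is_secondary = FALSE, is_virtual = FALSE,
                      peak_intensity = NA_real_))
  }
  primary <- peaks$intensity[1]
  ratios <- peaks$intensity / primary
  keep <- c(TRUE, ratios[-1] >= ratio_threshold)
  peaks <- peaks[keep, , drop = FALSE]
  ratios <- ratios[keep]
  data.frame(row = peaks$row, col = peaks$col,
             p_zdisc = c(p0, p0 * ratios[-1]),
             parent_contour_id = candidate$contour_id,
             is_secondary = c(FALSE, rep(TRUE, nrow(peaks) - 1)),
             is_virtual = FALSE,
             peak_intensity = peaks$intensity)
}
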