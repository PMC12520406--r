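#' Laplacian-of-Gaussian blob filter
#'
#' Convolves the image with a negated Laplacian-of-Gaussian kernel so that
#' bright blobs of width comparable to `sigma` become positive peaks. The
#' kernel is normalized to zero sum, so constant (and affine) regions map
#' to zero response. Convolution uses replicated-edge padding
#' (via \pkg{EBImage}).
#'
#' @param image numeric matrix of intensities.
#' @param sigma Gaussian scale of the kernel in pixels (> 0).
#' @return Numeric matrix of the same dimensions.
#' @export
log_filter <- function(image, sigma = 1) {
  stop_if_not_image(image)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  rad <- ceiling(4 * sigma)
  ax <- -rad:rad
  g <- exp(-ax^2 / (2 * sigma^2))
  G <- outer(g, g)
  r2 <- outer(ax^2, ax^2, `+`)
  k <- -((r2 - 2 * sigma^2) / sigma^4) * G   # negated LoG
  k <- k - mean(k)                           # exact zero response on constants
  out <- EBImage::filter2(image, k, boundary = "replicate")
  # filter2 returns an Image/array; keep a plain matrix
  matrix(as.numeric(out), nrow(image), ncol(image))
}

#' Otsu threshold
#'
#' Finds the threshold maximizing the between-class variance of the pixel
#' intensity distribution, by an exhaustive scan over all candidate cut
#' points (midpoints between consecutive distinct values). If a cell mask
#' is supplied, only pixels inside the mask enter the histogram.
#'
#' @param image numeric matrix.
#' @param mask optional logical matrix of the same dimensions.
#' @return A list with `mask` (logical matrix, `image > threshold`) and
#'   `threshold`.
#' @export
binarize_otsu <- function(image, mask = NULL) {
  stop_if_not_image(image)
  vals <- if (is.null(mask)) as.numeric(image) else {
    if (!identical(dim(mask), dim(image)))
      stop("`mask` dimensions must match `image`", call. = FALSE)
    as.numeric(image[mask])
  }
  u <- sort(unique(vals))
  if (length(u) < 2)
    stop("image is constant (fewer than 2 distinct values); ",
         "no Otsu threshold exists", call. = FALSE)
  cuts <- (u[-1] + u[-length(u)]) / 2
  n <- length(vals)
  sv <- sort(vals)
  csum <- cumsum(sv)
  # for each cut, number of values <= cut
  k <- findInterval(cuts, sv)
  w0 <- k / n
  w1 <- 1 - w0
  mu0 <- csum[k] / k
  mu1 <- (csum[n] - csum[k]) / (n - k)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  thr <- cuts[which.max(bcv)]
  list(mask = image > thr, threshold = thr)
}

#' Extract iso-contours by marching squares
#'
#' Traces sub-pixel iso-lines of the image at the given level (via
#' \pkg{isoband}, a marching-squares implementation) and keeps the closed
#' ones. Each contour carries its vertex polygon in 0-based (row, col)
#' coordinates, perimeter, enclosed area (shoelace), and centroid (mean of
#' vertices).
#'
#' @param filtered numeric matrix (typically the LoG-filtered image).
#' @param level iso-level; defaults to the Otsu threshold of `filtered`.
#' @return A list of `sarc_contour` objects.
#' @export
extract_contours <- function(filtered, level = NULL) {
  stop_if_not_image(filtered)
  if (is.null(level)) level <- binarize_otsu(filtered)$threshold
  rng <- range(filtered)
  if (level < rng[1] || level > rng[2])
    stop("`level` must lie within the image value range", call. = FALSE)
  nr <- nrow(filtered); nc <- ncol(filtered)
  iso <- isoband::isolines(x = 0:(nc - 1), y = 0:(nr - 1), z = filtered,
                           levels = level)[[1]]
  contours <- list()
  if (length(iso$id) == 0) return(contours)
  for (id in unique(iso$id)) {
    sel <- iso$id == id
    v <- cbind(row = iso$y[sel], col = iso$x[sel])
    n <- nrow(v)
    if (n < 4) next
    closed <- isTRUE(all.equal(v[1, ], v[n, ], tolerance = 1e-8,
                               check.attributes = FALSE))
    if (!closed) next        # open lines touch the image border
    v <- v[-n, , drop = FALSE]
    if (nrow(v) < 3) next
    contours[[length(contours) + 1L]] <- structure(list(
      id = length(contours) + 1L,
      vertices = v,
      perimeter = polygon_perimeter(v),
      area = polygon_area(v),
      centroid = colMeans(v)
    ), class = "sarc_contour")
  }
  contours
}

#' @export
print.sarc_contour <- function(x, ...) {
  cat(sprintf(
    "Contour %d: %d vertices, perimeter %.1f px, area %.1f px^2, centroid (%.1f, %.1f)\n",
    x$id, nrow(x$vertices), x$perimeter, x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Filter contours by perimeter
#'
#' Keeps contours whose polygon perimeter lies in `[min_len, max_len]`
#' (inclusive). The defaults reject contours shorter than 15 px or longer
#' than 200 px, the length gate used to discard specks and large fused
#' regions before classification.
#'
#' @param contours list of contours from [extract_contours()].
#' @param min_len,max_len perimeter bounds in pixels.
#' @return Filtered list of contours (ids reassigned sequentially).
#' @export
filter_contours_by_length <- function(contours, min_len = 15, max_len = 200) {
  if (min_len >= max_len) stop("`min_len` must be < `max_len`", call. = FALSE)
  keep <- vapply(contours, function(ct)
    ct$perimeter >= min_len && ct$perimeter <= max_len, logical(1))
  out <- contours[keep]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Write contours to CSV
#'
#' One row per vertex: `contour_id, vertex, row, col, perimeter, area,
#' centroid_row, centroid_col`.
#'
#' @param contours list of contours.
#' @param path output CSV path.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(contours, function(ct) {
    data.frame(contour_id = ct$id, vertex = seq_len(nrow(ct$vertices)),
               row = ct$vertices[, 1], col = ct$vertices[, 2],
               perimeter = ct$perimeter, area = ct$area,
               centroid_row = unname(ct$centroid[1]),
               centroid_col = unname(ct$centroid[2]))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contour_id = integer(0), vertex = integer(0), row = numeric(0),
               col = numeric(0), perimeter = numeric(0), area = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
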