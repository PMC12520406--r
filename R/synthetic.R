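#' Specification for a synthetic cardiomyocyte image
#'
#' Describes a synthetic single-cell alpha-actinin image: chains of
#' elongated z-disc blobs (myofibrils), round puncta (immature z-bodies),
#' and pixelwise Gaussian noise over a flat background. The defaults
#' emulate the imaging regime the pipeline targets: sarcomere spacing of
#' 13 px with 1 px jitter, z-discs elongated perpendicular to the chain
#' direction, and blob amplitude well above the noise floor.
#'
#' @param image_height,image_width image dimensions in pixels.
#' @param n_myofibrils number of z-disc chains to render.
#' @param sarcomeres_per_myofibril sarcomere count per chain; a single
#'   count or a length-2 range sampled uniformly per chain.
#' @param sarcomere_spacing_mean,sarcomere_spacing_sd spacing between
#'   consecutive z-discs along a chain, in pixels.
#' @param zdisc_sigma_long,zdisc_sigma_short Gaussian axes of a z-disc
#'   blob in pixels; the long axis lies perpendicular to the chain.
#' @param zdisc_amplitude peak intensity of a z-disc blob.
#' @param orientation_mode `"single-axis"` (all chains share one axis with
#'   angular jitter) or `"random"` (independent uniform orientation per
#'   chain).
#' @param orientation_angle base chain orientation in radians
#'   (single-axis mode).
#' @param orientation_jitter_sd angular jitter SD in radians
#'   (single-axis mode).
#' @param n_puncta number of round puncta.
#' @param puncta_sigma,puncta_amplitude Gaussian sigma and peak intensity
#'   of a punctum.
#' @param noise_sd SD of additive pixelwise Gaussian noise.
#' @param background_level constant background intensity.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   image and ground truth.
#' @return A `synthetic_cell_spec` list.
#' @seealso [generate_cell()]
#' @export
synthetic_cell_spec <- function(image_height = 256, image_width = 256,
                                n_myofibrils = 5,
                                sarcomeres_per_myofibril = 8,
                                sarcomere_spacing_mean = 13,
                                sarcomere_spacing_sd = 1,
                                zdisc_sigma_long = 2.5,
                                zdisc_sigma_short = 1.0,
                                zdisc_amplitude = 10,
                                orientation_mode = c("single-axis", "random"),
                                orientation_angle = pi / 4,
                                orientation_jitter_sd = 5 * pi / 180,
                                n_puncta = 30,
                                puncta_sigma = 1.2,
                                puncta_amplitude = 10,
                                noise_sd = 1,
                                background_level = 1,
                                seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  spec <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_myofibrils = as.integer(n_myofibrils),
    sarcomeres_per_myofibril = as.integer(sarcomeres_per_myofibril),
    sarcomere_spacing_mean = sarcomere_spacing_mean,
    sarcomere_spacing_sd = sarcomere_spacing_sd,
    zdisc_sigma_long = zdisc_sigma_long,
    zdisc_sigma_short = zdisc_sigma_short,
    zdisc_amplitude = zdisc_amplitude,
    orientation_mode = orientation_mode,
    orientation_angle = orientation_angle,
    orientation_jitter_sd = orientation_jitter_sd,
    n_puncta = as.integer(n_puncta),
    puncta_sigma = puncta_sigma,
    puncta_amplitude = puncta_amplitude,
    noise_sd = noise_sd,
    background_level = background_level,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_cell_spec"
  validate_cell_spec(spec)
  spec
}

validate_cell_spec <- function(spec) {
  with(spec, {
    if (image_height <= 0 || image_width <= 0)
      stop("image dimensions must be positive", call. = FALSE)
    if (n_myofibrils < 0 || n_puncta < 0)
      stop("structure counts must be non-negative", call. = FALSE)
    if (any(sarcomeres_per_myofibril < 1) && n_myofibrils > 0)
      stop("each myofibril needs at least one sarcomere", call. = FALSE)
    if (zdisc_sigma_long <= 0 || zdisc_sigma_short <= 0 || puncta_sigma <= 0)
      stop("blob sigmas must be positive", call. = FALSE)
    if (noise_sd < 0 || background_level < 0)
      stop("noise_sd and background_level must be non-negative", call. = FALSE)
    lo <- sarcomere_spacing_mean - 3 * sarcomere_spacing_sd
    hi <- sarcomere_spacing_mean + 3 * sarcomere_spacing_sd
    if (lo <= 0 || hi >= min(image_height, image_width))
      stop("sarcomere spacing mean +/- 3 sd must stay within (0, min image dim)",
           call. = FALSE)
    if (n_myofibrils > 0) {
      n_max <- max(sarcomeres_per_myofibril)
      margin <- 4 * max(zdisc_sigma_long, zdisc_sigma_short)
      if (n_max * hi + 2 * margin >= min(image_height, image_width))
        stop("a myofibril chain of the requested length cannot be placed ",
             "inside the image frame", call. = FALSE)
    }
  })
  invisible(spec)
}

# Add one anisotropic Gaussian blob in place. `axis_dir` is the unit vector
# of the *short* axis (the chain direction for z-discs).
render_blob <- function(image, center, amplitude, sigma_short, sigma_long,
                        axis_dir) {
  nr <- nrow(image); nc <- ncol(image)
  rad <- ceiling(4 * max(sigma_short, sigma_long))
  r0 <- max(0L, floor(center[1]) - rad); r1 <- min(nr - 1L, ceiling(center[1]) + rad)
  c0 <- max(0L, floor(center[2]) - rad); c1 <- min(nc - 1L, ceiling(center[2]) + rad)
  if (r1 < r0 || c1 < c0) return(image)
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  along <- dr * axis_dir[1] + dc * axis_dir[2]
  perp <- -dr * axis_dir[2] + dc * axis_dir[1]
  g <- amplitude * exp(-(along^2 / (2 * sigma_short^2) +
                           perp^2 / (2 * sigma_long^2)))
  image[rr + 1, cc + 1] <- image[rr + 1, cc + 1] + g
  image
}

#' Generate a synthetic cardiomyocyte image with exact ground truth
#'
#' Renders the structures described by a [synthetic_cell_spec()]: myofibril
#' chains of anisotropic Gaussian z-disc blobs at the requested spacing,
#' isotropic puncta, additive Gaussian noise, and a flat background
#' (clipped to non-negative intensities). The returned ground truth records
#' every rendered blob center, whether it is a true z-disc or a punctum,
#' the sarcomere pairs, and the ordered myofibril chains.
#'
#' @param spec a [synthetic_cell_spec()].
#' @return An object of class `synthetic_cell`: a list with elements
#'   `image` (numeric matrix), `ground_truth` (list with `centers` -- an
#'   n x 2 matrix of 0-based (row, col) sub-pixel coordinates, `is_zdisc`
#'   logical vector, `pairs` -- m x 2 matrix of 1-based center indices,
#'   `chains` -- list of ordered index vectors), and `spec`.
#' @examples
#' cell <- generate_cell(synthetic_cell_spec(n_myofibrils = 2, seed = 7))
#' dim(cell$image)
#' nrow(cell$ground_truth$centers)
#' @export
generate_cell <- function(spec) {
  if (!inherits(spec, "synthetic_cell_spec"))
    stop("`spec` must be a synthetic_cell_spec", call. = FALSE)
  validate_cell_spec(spec)
  set.seed(spec$seed)
  nr <- spec$image_height; nc <- spec$image_width
  image <- matrix(spec$background_level, nr, nc)
  margin <- 4 * max(spec$zdisc_sigma_long, spec$zdisc_sigma_short)

  centers <- NULL; is_zdisc <- logical(0)
  pairs <- NULL; chains <- list()

  for (m in seq_len(spec$n_myofibrils)) {
    n_s <- if (length(spec$sarcomeres_per_myofibril) > 1) {
      sample(spec$sarcomeres_per_myofibril[1]:spec$sarcomeres_per_myofibril[2], 1)
    } else spec$sarcomeres_per_myofibril
    n_z <- n_s + 1L
    phi <- switch(spec$orientation_mode,
      "single-axis" = spec$orientation_angle +
        rnorm(1, 0, spec$orientation_jitter_sd),
      "random" = runif(1, 0, pi))
    dir <- c(sin(phi), cos(phi))
    spacings <- rnorm(n_s, spec$sarcomere_spacing_mean,
                      spec$sarcomere_spacing_sd)
    spacings <- clamp(spacings,
                      spec$sarcomere_spacing_mean - 3 * spec$sarcomere_spacing_sd,
                      spec$sarcomere_spacing_mean + 3 * spec$sarcomere_spacing_sd)
    offsets <- c(0, cumsum(spacings))
    placed <- FALSE
    for (try in seq_len(200)) {
      start <- c(runif(1, margin, nr - 1 - margin),
                 runif(1, margin, nc - 1 - margin))
      pos <- cbind(start[1] + offsets * dir[1], start[2] + offsets * dir[2])
      if (all(pos[, 1] >= margin & pos[, 1] <= nr - 1 - margin &
                pos[, 2] >= margin & pos[, 2] <= nc - 1 - margin)) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("failed to place myofibril chain ", m,
           " inside the image frame; reduce chain length or enlarge the image",
           call. = FALSE)
    idx0 <- if (is.null(centers)) 0L else nrow(centers)
    centers <- rbind(centers, pos)
    is_zdisc <- c(is_zdisc, rep(TRUE, n_z))
    chain_idx <- idx0 + seq_len(n_z)
    chains[[length(chains) + 1L]] <- chain_idx
    pairs <- rbind(pairs, cbind(chain_idx[-n_z], chain_idx[-1]))
    for (i in seq_len(n_z)) {
      image <- render_blob(image, pos[i, ], spec$zdisc_amplitude,
                           spec$zdisc_sigma_short, spec$zdisc_sigma_long, dir)
    }
  }

  for (p in seq_len(spec$n_puncta)) {
    ctr <- c(runif(1, margin, nr - 1 - margin),
             runif(1, margin, nc - 1 - margin))
    centers <- rbind(centers, matrix(ctr, 1))
    is_zdisc <- c(is_zdisc, FALSE)
    image <- render_blob(image, ctr, spec$puncta_amplitude,
                         spec$puncta_sigma, spec$puncta_sigma, c(0, 1))
  }

  if (spec$noise_sd > 0)
    image <- image + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  image <- pmax(image, 0)

  if (is.null(centers)) centers <- matrix(numeric(0), 0, 2)
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  colnames(centers) <- c("row", "col")
  colnames(pairs) <- c("a", "b")
  structure(list(
    image = image,
    ground_truth = list(centers = centers, is_zdisc = is_zdisc,
                        pairs = pairs, chains = chains),
    spec = spec
  ), class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  gt <- x$ground_truth
  cat("Synthetic cardiomyocyte image ", nrow(x$image), " x ", ncol(x$image),
      "\n", sep = "")
  cat("  z-discs: ", sum(gt$is_zdisc), "  puncta: ", sum(!gt$is_zdisc),
      "  sarcomeres: ", nrow(gt$pairs), "  myofibrils: ", length(gt$chains),
      "\n", sep = "")
  invisible(x)
}

#' Generate labeled contour crops from synthetic images
#'
#' Runs z-disc segmentation on freshly generated synthetic images and labels
#' each surviving contour by the nearest ground-truth blob: a contour whose
#' centroid lies within `match_radius` of a chain z-disc center becomes a
#' "zdisc" example, within `match_radius` of a punctum a "not_zdisc"
#' example; ambiguous contours are discarded. Images are drawn (with
#' consecutive seeds derived from the spec seed) until both classes reach
#' `n_per_class` crops.
#'
#' The contour-length bounds default to the synthetic blob scale (the
#' generator's blobs are a few pixels across) rather than the pipeline's
#' real-image defaults.
#'
#' @param spec a [synthetic_cell_spec()]; must request both myofibrils and
#'   puncta, otherwise one class is impossible and an error is raised.
#' @param n_per_class minimum number of crops per class.
#' @param max_draws maximum number of images to generate before giving up.
#' @param match_radius centroid-to-center labeling radius in pixels.
#' @param min_len,max_len contour perimeter bounds used during segmentation.
#' @param log_sigma LoG filter sigma.
#' @param crop_size crop side length in pixels.
#' @return A list with `crops` (list of [build_crop()] objects), `labels`
#'   (factor with levels `zdisc`, `not_zdisc`), `draw` (the image draw
#'   each crop came from; its seed is `spec$seed + draw - 1`), and
#'   `n_draws`.
#' @export
generate_labeled_crops <- function(spec, n_per_class, max_draws = 25,
                                   match_radius = 3, min_len = 6,
                                   max_len = 200, log_sigma = 1,
                                   crop_size = 128) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  if (spec$n_myofibrils < 1)
    stop("spec has no myofibrils: the 'zdisc' class cannot be produced",
         call. = FALSE)
  if (spec$n_puncta < 1)
    stop("spec has no puncta: the 'not_zdisc' class cannot be produced",
         call. = FALSE)
  crops <- list(); labels <- character(0); draws <- integer(0)
  n_pos <- 0L; n_neg <- 0L
  for (draw in seq_len(max_draws)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + draw - 1L
    cell <- generate_cell(spec_i)
    gt <- cell$ground_truth
    filt <- log_filter(cell$image, sigma = log_sigma)
    thr <- tryCatch(binarize_otsu(filt)$threshold, error = function(e) NULL)
    if (is.null(thr)) next
    contours <- filter_contours_by_length(extract_contours(filt, thr),
                                          min_len, max_len)
    if (length(contours) == 0) next
    raster <- rasterize_contours(contours, nrow(cell$image), ncol(cell$image))
    cents <- t(vapply(contours, function(ct) ct$centroid, numeric(2)))
    for (i in seq_along(contours)) {
      d <- sqrt((gt$centers[, 1] - cents[i, 1])^2 +
                  (gt$centers[, 2] - cents[i, 2])^2)
      if (length(d) == 0 || min(d) > match_radius) next
      lab <- if (gt$is_zdisc[which.min(d)]) "zdisc" else "not_zdisc"
      if (lab == "zdisc" && n_pos >= n_per_class) next
      if (lab == "not_zdisc" && n_neg >= n_per_class) next
      crop <- build_crop(cell$image, contours, i, filtered = filt,
                         size = crop_size, raster = raster)
      crops[[length(crops) + 1L]] <- crop
      labels <- c(labels, lab)
      draws <- c(draws, draw)
      if (lab == "zdisc") n_pos <- n_pos + 1L else n_neg <- n_neg + 1L
    }
    if (n_pos >= n_per_class && n_neg >= n_per_class) break
  }
  if (n_pos < n_per_class || n_neg < n_per_class)
    stop("could not collect ", n_per_class, " crops per class within ",
         max_draws, " image draws (got ", n_pos, " zdisc / ", n_neg,
         " not_zdisc); check the spec's structure counts", call. = FALSE)
  list(crops = crops, labels = factor(labels, levels = c("zdisc", "not_zdisc")),
       draw = draws, n_draws = draw)
}
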