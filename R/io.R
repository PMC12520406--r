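# Image and table I/O: TIFF/PNG images, CSV tables, JSON ground truth,
# graph dumps, and run manifests.

#' Read a grayscale cell image
#'
#' Reads a TIFF or PNG image as a numeric matrix. Multi-channel images
#' are reduced to their first channel.
#'
#' @param path image path (`.tif`, `.tiff`, or `.png`).
#' @return Numeric matrix of intensities.
#' @export
read_cell_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Write a grayscale image as 32-bit float TIFF
#'
#' @param image numeric matrix.
#' @param path output path.
#' @export
write_cell_image <- function(image, path) {
  stop_if_not_image(image)
  tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write synthetic ground truth as JSON
#'
#' @param ground_truth the `ground_truth` element of a [generate_cell()]
#'   result.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  obj <- list(
    centers = unname(apply(ground_truth$centers, 1, as.numeric,
                           simplify = FALSE)),
    is_zdisc = ground_truth$is_zdisc,
    pairs = unname(apply(ground_truth$pairs, 1, as.integer,
                         simplify = FALSE)),
    chains = lapply(ground_truth$chains, as.integer)
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_matrix <- function(lst, ncol) {
    if (length(lst) == 0) return(matrix(numeric(0), 0, ncol))
    do.call(rbind, lapply(lst, unlist))
  }
  centers <- to_matrix(obj$centers, 2)
  pairs <- to_matrix(obj$pairs, 2)
  storage.mode(pairs) <- "integer"
  colnames(centers) <- c("row", "col"); colnames(pairs) <- c("a", "b")
  list(centers = centers, is_zdisc = as.logical(unlist(obj$is_zdisc)),
       pairs = pairs,
       chains = lapply(obj$chains, function(ch) as.integer(unlist(ch))))
}

#' Write all detection tables to a directory
#'
#' Writes `contours.csv`, `zdiscs.csv`, `sarcomeres.csv`,
#' `myofibrils.csv`, a JSON graph dump (`graph.json`), and a run manifest
#' (`manifest.json` with the resolved configuration). Coordinates are
#' 0-based (row, col).
#'
#' @param detection a `sarc_detection`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_detection <- function(detection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contours_csv(detection$contours, file.path(dir, "contours.csv"))

  zd <- detection$zdiscs
  zd$zdisc_id <- seq_len(nrow(zd))
  write.csv(zd[, c("zdisc_id", "row", "col", "p_zdisc",
                   "parent_contour_id", "is_secondary", "is_virtual",
                   "peak_intensity")],
            file.path(dir, "zdiscs.csv"), row.names = FALSE)

  E <- detection$edges
  E$edge_id <- seq_len(nrow(E))
  E$row_a <- zd$row[E$a]; E$col_a <- zd$col[E$a]
  E$row_b <- zd$row[E$b]; E$col_b <- zd$col[E$b]
  write.csv(E[, c("edge_id", "a", "b", "row_a", "col_a", "row_b", "col_b",
                  "length", "orientation", "s_original", "s_validity",
                  "s_zprob", "s_alignment", "p_ensemble", "validity_class",
                  "myofibril_id", "position_in_myofibril")],
            file.path(dir, "sarcomeres.csv"), row.names = FALSE)

  myo <- if (length(detection$myofibrils)) {
    do.call(rbind, lapply(seq_along(detection$myofibrils), function(m) {
      ch <- detection$myofibrils[[m]]
      data.frame(myofibril_id = m, position = seq_along(ch), zdisc_id = ch)
    }))
  } else data.frame(myofibril_id = integer(0), position = integer(0),
                    zdisc_id = integer(0))
  write.csv(myo, file.path(dir, "myofibrils.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(nodes = zd, edges = E),
    file.path(dir, "graph.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  jsonlite::write_json(
    list(package = "myograph",
         version = as.character(utils::packageVersion("myograph")),
         config = unclass_config(detection$config),
         otsu_threshold = detection$otsu_threshold,
         image_dim = detection$dim,
         n_contours = length(detection$contours),
         n_zdiscs = nrow(zd),
         n_sarcomeres = nrow(final_sarcomeres(detection)),
         n_myofibrils = length(detection$myofibrils)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$scoring <- unclass(cfg$scoring)
  cfg
}
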