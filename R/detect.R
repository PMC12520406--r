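# The end-to-end detection pipeline and its classed result object.

#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default.
#' Defaults follow the intended real-image operating point: LoG sigma
#' 1 px, contour perimeter bounds 15-200 px, classifier probability
#' threshold 0.3, secondary-peak ratio 0.6, mutual-kNN N = 3, sarcomere
#' length range 10-20 px around an average of 15 px, extension rules
#' 7 px / [10, 20] px / 22.5 degrees with up to 3 passes.
#'
#' @param log_sigma LoG filter sigma (px).
#' @param min_contour_length,max_contour_length contour perimeter gate (px).
#' @param prob_threshold classifier probability cutoff.
#' @param sigma_smooth localization smoothing sigma (px).
#' @param n_starts random ascent starts per contour.
#' @param peak_merge_radius merge radius for converged peaks (px).
#' @param secondary_ratio secondary-peak intensity ratio cutoff.
#' @param scoring a [scoring_config()].
#' @param ext_match_radius,ext_length_bounds,ext_max_turn_deg,ext_p_min,ext_max_iter
#'   myofibril-extension rules.
#' @param crop_size classifier crop side length (px).
#' @param seed pipeline-level seed; per-contour localization seeds are
#'   derived from it.
#' @return A `sarc_config` list.
#' @export
sarc_config <- function(log_sigma = 1,
                        min_contour_length = 15, max_contour_length = 200,
                        prob_threshold = 0.3,
                        sigma_smooth = 1, n_starts = 10,
                        peak_merge_radius = 1.5, secondary_ratio = 0.6,
                        scoring = scoring_config(),
                        ext_match_radius = 7, ext_length_bounds = c(10, 20),
                        ext_max_turn_deg = 22.5, ext_p_min = 0.5,
                        ext_max_iter = 3,
                        crop_size = 128, seed = 1L) {
  structure(list(
    log_sigma = log_sigma, min_contour_length = min_contour_length,
    max_contour_length = max_contour_length, prob_threshold = prob_threshold,
    sigma_smooth = sigma_smooth, n_starts = n_starts,
    peak_merge_radius = peak_merge_radius, secondary_ratio = secondary_ratio,
    scoring = scoring,
    ext_match_radius = ext_match_radius,
    ext_length_bounds = ext_length_bounds,
    ext_max_turn_deg = ext_max_turn_deg, ext_p_min = ext_p_min,
    ext_max_iter = ext_max_iter,
    crop_size = crop_size, seed = as.integer(seed)
  ), class = "sarc_config")
}

empty_zdisc_df <- function() {
  data.frame(row = numeric(0), col = numeric(0), p_zdisc = numeric(0),
             parent_contour_id = integer(0), is_secondary = logical(0),
             is_virtual = logical(0), peak_intensity = numeric(0))
}

empty_edge_df <- function() {
  data.frame(a = integer(0), b = integer(0), length = numeric(0),
             orientation = numeric(0), s_original = numeric(0),
             s_validity = numeric(0), s_zprob = numeric(0),
             s_alignment = numeric(0), p_ensemble = numeric(0),
             validity_class = integer(0), myofibril_id = integer(0),
             position_in_myofibril = integer(0))
}

#' Detect z-discs, sarcomeres, and myofibrils in a cell image
#'
#' Runs the full pipeline: LoG filtering, Otsu binarization,
#' marching-squares contour extraction, perimeter filtering, crop
#' classification with the supplied classifier pair, probability
#' filtering, sub-pixel peak localization (with contour splitting via the
#' secondary-peak rule), mutual-kNN graph construction, four-way edge
#' scoring fused by probabilistic ensemble averaging, pruning, myofibril
#' assembly, gap-bridging extension, and singleton removal.
#'
#' @param image numeric matrix of raw intensities (or a `synthetic_cell`,
#'   whose image is used).
#' @param classifier1,classifier2 classifier pair (objects with a
#'   [predict()] method over crops), e.g. from
#'   [train_baseline_classifier()] or [oracle_classifier()].
#' @param config a [sarc_config()].
#' @param cell_mask optional logical matrix restricting the Otsu
#'   histogram; its area also becomes the default cell area.
#' @return A `sarc_detection` object: list with `contours`, `candidates`
#'   (contour table with `p1`, `p2`, `p_zdisc`, `area`, `kept`), `zdiscs`
#'   (localized z-disc table, including virtual nodes), `edges` (scored
#'   sarcomere table), `myofibrils` (list of ordered z-disc id chains),
#'   `n_sarcomeres_before_extension`, `otsu_threshold`, `config`,
#'   `cell_area`, and the image dimensions.
#' @examples
#' cell <- generate_cell(synthetic_cell_spec(n_myofibrils = 3, n_puncta = 10,
#'                                           seed = 2))
#' clf <- oracle_classifier(cell$ground_truth)
#' det <- detect_sarcomeres(cell$image, clf, clf,
#'                          config = sarc_config(min_contour_length = 6))
#' det
#' @export
detect_sarcomeres <- function(image, classifier1, classifier2,
                              config = sarc_config(), cell_mask = NULL) {
  if (inherits(image, "synthetic_cell")) image <- image$image
  stop_if_not_image(image)
  cell_area <- if (!is.null(cell_mask)) sum(cell_mask) else
    nrow(image) * ncol(image)

  res <- structure(list(
    dim = dim(image), config = config, cell_area = cell_area,
    contours = list(),
    candidates = data.frame(contour_id = integer(0), p1 = numeric(0),
                            p2 = numeric(0), p_zdisc = numeric(0),
                            area = numeric(0), kept = logical(0)),
    zdiscs = empty_zdisc_df(), edges = empty_edge_df(),
    myofibrils = list(), n_sarcomeres_before_extension = 0L,
    otsu_threshold = NA_real_
  ), class = "sarc_detection")

  # --- z-disc segmentation -------------------------------------------------
  filt <- log_filter(image, config$log_sigma)
  ots <- tryCatch(binarize_otsu(filt, mask = cell_mask),
                  error = function(e) NULL)
  if (is.null(ots)) {
    warning("image appears empty (no Otsu threshold); returning an empty ",
            "detection")
    return(res)
  }
  res$otsu_threshold <- ots$threshold
  contours <- filter_contours_by_length(
    extract_contours(filt, ots$threshold),
    config$min_contour_length, config$max_contour_length)
  res$contours <- contours
  if (length(contours) == 0) {
    warning("no contours survived the length filter")
    return(res)
  }

  # --- classification ------------------------------------------------------
  crops <- build_crops(image, contours, filtered = filt,
                       size = config$crop_size)
  cand <- classify_candidates(crops, classifier1, classifier2)
  cand$area <- vapply(contours, `[[`, numeric(1), "area")
  cand$kept <- cand$p_zdisc >= config$prob_threshold
  res$candidates <- cand
  kept_idx <- which(cand$kept)
  if (length(kept_idx) == 0) {
    warning("no candidates above the probability threshold")
    return(res)
  }

  # --- localization --------------------------------------------------------
  surface <- smooth_surface(image, config$sigma_smooth)
  zd_list <- lapply(kept_idx, function(i) {
    peaks <- tryCatch(
      find_peaks_in_contour(surface, contours[[i]],
                            n_starts = config$n_starts,
                            seed = config$seed + cand$contour_id[i],
                            merge_radius = config$peak_merge_radius),
      error = function(e) data.frame(row = numeric(0), col = numeric(0),
                                     intensity = numeric(0)))
    assign_zdiscs(peaks, cand[i, ], contours[[i]],
                  ratio_threshold = config$secondary_ratio)
  })
  zdiscs <- do.call(rbind, zd_list)
  rownames(zdiscs) <- NULL
  res$zdiscs <- zdiscs

  # --- sarcomere detection -------------------------------------------------
  graph <- build_candidate_graph(zdiscs, config$scoring$N_neighbors)
  E <- graph$edges
  if (nrow(E) == 0) {
    res$zdiscs <- zdiscs
    return(res)
  }
  adj <- edge_adjacency(graph)
  s_orig <- score_original(graph, config$scoring, adjacency = adj)
  s_val <- score_pruning_validity(graph, config$scoring,
                                  s_original = s_orig, adjacency = adj)
  s_zp <- score_zdisc_probability(graph)
  s_al <- score_global_alignment(graph, config$scoring, adjacency = adj)
  p_ens <- ensemble_scores(cbind(s_orig, s_val, s_zp, s_al), config$scoring)
  pruned <- prune_graph(graph, p_ens, s_accept = config$scoring$s_accept,
                        s_strong = config$scoring$s_strong)

  myos <- assemble_myofibrils(graph, pruned$retained, p_ens)
  res$n_sarcomeres_before_extension <-
    sum(vapply(myos, function(ch) length(ch) - 1L, integer(1)))
  ext <- extend_myofibrils(myos, zdiscs,
                           match_radius = config$ext_match_radius,
                           length_bounds = config$ext_length_bounds,
                           max_turn_deg = config$ext_max_turn_deg,
                           p_min = config$ext_p_min,
                           max_iterations = config$ext_max_iter)
  myos <- drop_singletons(ext$myofibrils)
  res$zdiscs <- ext$zdiscs
  res$myofibrils <- myos

  E$s_original <- s_orig; E$s_validity <- s_val
  E$s_zprob <- s_zp; E$s_alignment <- s_al
  E$p_ensemble <- p_ens; E$validity_class <- pruned$validity
  E$myofibril_id <- NA_integer_; E$position_in_myofibril <- NA_integer_
  res$edges <- E
  res$edges <- annotate_myofibril_edges(res)
  res
}

# Rebuild the edge table so every sarcomere of the final myofibrils
# (including extension-created ones) appears with its myofibril id and
# position.
annotate_myofibril_edges <- function(det) {
  E <- det$edges
  zd <- det$zdiscs
  key <- paste(pmin(E$a, E$b), pmax(E$a, E$b))
  extra <- list()
  for (m in seq_along(det$myofibrils)) {
    ch <- det$myofibrils[[m]]
    for (i in seq_len(length(ch) - 1)) {
      a <- ch[i]; b <- ch[i + 1]
      k <- paste(min(a, b), max(a, b))
      hit <- match(k, key)
      if (!is.na(hit)) {
        E$myofibril_id[hit] <- m
        E$position_in_myofibril[hit] <- i
      } else {
        dr <- zd$row[b] - zd$row[a]; dc <- zd$col[b] - zd$col[a]
        extra[[length(extra) + 1L]] <- data.frame(
          a = a, b = b, length = sqrt(dr^2 + dc^2),
          orientation = segment_orientation(dr, dc),
          s_original = NA_real_, s_validity = NA_real_,
          s_zprob = NA_real_, s_alignment = NA_real_,
          p_ensemble = NA_real_, validity_class = 1L,
          myofibril_id = m, position_in_myofibril = i)
      }
    }
  }
  if (length(extra)) E <- rbind(E, do.call(rbind, extra))
  rownames(E) <- NULL
  E
}

#' Final detected sarcomeres
#'
#' The sarcomeres belonging to the final myofibrils (after extension and
#' singleton removal), as rows of the edge table.
#'
#' @param detection a `sarc_detection`.
#' @return data.frame of edges with non-missing `myofibril_id`.
#' @export
final_sarcomeres <- function(detection) {
  E <- detection$edges
  E[!is.na(E$myofibril_id), , drop = FALSE]
}

#' @export
print.sarc_detection <- function(x, ...) {
  n_sarc <- nrow(final_sarcomeres(x))
  cat("Sarcomere detection result (", x$dim[1], " x ", x$dim[2],
      " image)\n", sep = "")
  cat("  contours: ", length(x$contours),
      "  candidates kept: ", sum(x$candidates$kept),
      "  z-discs: ", nrow(x$zdiscs), "\n", sep = "")
  cat("  sarcomeres: ", n_sarc, "  myofibrils: ", length(x$myofibrils),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.sarc_detection <- function(object, ...) {
  sarc <- final_sarcomeres(object)
  lens <- vapply(object$myofibrils, function(ch) length(ch) - 1L, integer(1))
  cat("Sarcomere detection summary\n")
  cat("  image: ", object$dim[1], " x ", object$dim[2],
      "  Otsu threshold: ", signif(object$otsu_threshold, 4), "\n", sep = "")
  cat("  contours after length filter: ", length(object$contours),
      "\n", sep = "")
  cat("  candidates >= ", object$config$prob_threshold, ": ",
      sum(object$candidates$kept), " of ", nrow(object$candidates),
      "\n", sep = "")
  cat("  z-discs: ", nrow(object$zdiscs), " (",
      sum(object$zdiscs$is_secondary), " secondary, ",
      sum(object$zdiscs$is_virtual), " virtual)\n", sep = "")
  cat("  sarcomeres: ", nrow(sarc), " (",
      object$n_sarcomeres_before_extension, " before extension)\n", sep = "")
  if (nrow(sarc)) {
    cat(sprintf("  sarcomere length: %.2f +/- %.2f px\n",
                mean(sarc$length),
                if (nrow(sarc) > 1) sd(sarc$length) else 0))
    cat(sprintf("  orientational order parameter: %.3f\n",
                orientation_order_parameter(sarc$orientation)))
  }
  cat("  myofibrils: ", length(object$myofibrils), sep = "")
  if (length(lens))
    cat(sprintf(" (mean length %.2f sarcomeres, max %d)", mean(lens),
                max(lens)))
  cat("\n")
  invisible(object)
}

#' Plot a detection result
#'
#' Displays the sarcomeres (red segments) and z-discs (blue points;
#' virtual z-discs open circles) over the detection geometry.
#'
#' @param x a `sarc_detection`.
#' @param image optional raw image matrix to draw underneath.
#' @param ... passed to [graphics::image()].
#' @export
plot.sarc_detection <- function(x, image = NULL, ...) {
  nr <- x$dim[1]; nc <- x$dim[2]
  if (!is.null(image)) {
    graphics::image(x = 0:(nc - 1), y = 0:(nr - 1),
                    z = t(image[nr:1, , drop = FALSE]),
                    col = gray(seq(0, 1, length.out = 256)),
                    xlab = "col", ylab = "row", useRaster = TRUE, ...)
    flip <- function(r) nr - 1 - r
  } else {
    plot(NA, xlim = c(0, nc - 1), ylim = c(nr - 1, 0),
         xlab = "col", ylab = "row", asp = 1, ...)
    flip <- identity
  }
  zd <- x$zdiscs
  sarc <- final_sarcomeres(x)
  if (nrow(sarc))
    segments(zd$col[sarc$a], flip(zd$row[sarc$a]),
             zd$col[sarc$b], flip(zd$row[sarc$b]), col = "red", lwd = 2)
  if (nrow(zd))
    points(zd$col, flip(zd$row), pch = ifelse(zd$is_virtual, 1, 16),
           col = "blue", cex = 0.7)
  invisible(x)
}
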