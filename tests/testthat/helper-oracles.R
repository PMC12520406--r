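# Shared fixtures and independent oracles used across the test files.

# Independent Otsu oracle: plain nested computation of the between-class
# variance at every candidate cut (midpoints of consecutive unique values).
otsu_oracle <- function(vals) {
  u <- sort(unique(vals))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best_t <- NA; best_v <- -Inf
  for (t in cuts) {
    g0 <- vals[vals <= t]; g1 <- vals[vals > t]
    w0 <- length(g0) / length(vals); w1 <- 1 - w0
    v <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# Brute-force mutual-kNN oracle over a point matrix (row, col).
mutual_knn_oracle <- function(pts, N) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  diag(D) <- Inf
  edges <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ni <- order(D[i, ])[seq_len(min(N, n - 1))]
    nj <- order(D[j, ])[seq_len(min(N, n - 1))]
    if ((j %in% ni) && (i %in% nj)) edges <- rbind(edges, c(i, j))
  }
  if (is.null(edges)) matrix(integer(0), 0, 2) else edges
}

# Render one or more isotropic/anisotropic Gaussian blobs on a flat
# background; centers is an n x 2 matrix of 0-based (row, col).
render_blobs <- function(nr, nc, centers, amplitudes, sigmas,
                         background = 0) {
  img <- matrix(background, nr, nc)
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    img <- img + amplitudes[i] *
      exp(-((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2) /
            (2 * sigmas[i]^2))
  }
  img
}

# Rectangle contour (0-based, row/col bounds) as a sarc_contour.
rect_contour <- function(r0, r1, c0, c1, id = 1L) {
  v <- cbind(row = c(r0, r0, r1, r1), col = c(c0, c1, c1, c0))
  structure(list(id = id, vertices = v,
                 perimeter = 2 * (r1 - r0) + 2 * (c1 - c0),
                 area = (r1 - r0) * (c1 - c0),
                 centroid = colMeans(v)),
            class = "sarc_contour")
}

# A contour list with prescribed perimeters (geometry irrelevant).
fake_contours <- function(perimeters) {
  lapply(seq_along(perimeters), function(i) {
    ct <- rect_contour(0, 1, 0, 1, id = i)
    ct$perimeter <- perimeters[i]
    ct
  })
}

# A z-disc node table from a position matrix.
zdisc_table <- function(pos, p = rep(0.9, nrow(pos))) {
  data.frame(row = pos[, 1], col = pos[, 2], p_zdisc = p,
             parent_contour_id = seq_len(nrow(pos)),
             is_secondary = FALSE, is_virtual = FALSE,
             peak_intensity = NA_real_)
}

# A straight chain of n nodes spaced `spacing` px apart at angle phi.
chain_positions <- function(n, spacing = 13, phi = 0, origin = c(50, 20)) {
  k <- 0:(n - 1)
  cbind(origin[1] + k * spacing * sin(phi),
        origin[2] + k * spacing * cos(phi))
}

# Constant-output classifier satisfying the classifier contract (an
# oracle classifier with an empty ground truth always returns p_miss).
const_classifier <- function(p) {
  oracle_classifier(list(centers = matrix(numeric(0), 0, 2),
                         is_zdisc = logical(0)),
                    p_miss = p)
}

# Greedy one-to-one matching of detected sarcomeres to ground-truth pairs
# (both endpoints within `tol` px); returns c(n_matched, n_det, n_true).
match_sarcomeres <- function(det, gt, tol = 3) {
  sarc <- final_sarcomeres(det)
  used <- rep(FALSE, nrow(gt$pairs)); ok <- 0L
  for (i in seq_len(nrow(sarc))) {
    p1 <- c(det$zdiscs$row[sarc$a[i]], det$zdiscs$col[sarc$a[i]])
    p2 <- c(det$zdiscs$row[sarc$b[i]], det$zdiscs$col[sarc$b[i]])
    for (j in seq_len(nrow(gt$pairs))) {
      if (used[j]) next
      q1 <- gt$centers[gt$pairs[j, 1], ]; q2 <- gt$centers[gt$pairs[j, 2], ]
      hit <- (sqrt(sum((p1 - q1)^2)) <= tol &&
                sqrt(sum((p2 - q2)^2)) <= tol) ||
        (sqrt(sum((p1 - q2)^2)) <= tol && sqrt(sum((p2 - q1)^2)) <= tol)
      if (hit) { ok <- ok + 1L; used[j] <- TRUE; break }
    }
  }
  c(matched = ok, n_det = nrow(sarc), n_true = nrow(gt$pairs))
}

# Z-disc precision/recall of a detection against ground truth.
match_zdiscs <- function(det, gt, tol = 3) {
  zd <- det$zdiscs[!det$zdiscs$is_virtual, , drop = FALSE]
  tz <- gt$centers[gt$is_zdisc, , drop = FALSE]
  d2 <- outer(zd$row, tz[, 1], "-")^2 + outer(zd$col, tz[, 2], "-")^2
  c(matched_det = sum(apply(d2, 1, min) <= tol^2), n_det = nrow(zd),
    matched_true = sum(apply(d2, 2, min) <= tol^2), n_true = nrow(tz))
}

# Minimal detection object for feature tests.
detection_fixture <- function(lengths, orientations, n_myofibrils,
                              p_zdisc = numeric(0), areas = numeric(0),
                              cell_area = 1000) {
  n <- length(lengths)
  edges <- data.frame(
    a = seq_len(n), b = seq_len(n) + 1L, length = lengths,
    orientation = orientations, s_original = rep(0.9, n),
    s_validity = rep(0.99, n), s_zprob = rep(0.9, n),
    s_alignment = rep(0.5, n), p_ensemble = rep(0.9, n),
    validity_class = rep(2L, n),
    myofibril_id = if (n) rep(seq_len(max(1, n_myofibrils)),
                              length.out = n) else integer(0),
    position_in_myofibril = seq_len(n))
  structure(list(
    dim = c(100, 100), cell_area = cell_area,
    candidates = data.frame(contour_id = seq_along(p_zdisc),
                            p_zdisc = p_zdisc, area = areas,
                            kept = p_zdisc >= 0.3),
    zdiscs = zdisc_table(matrix(0, n + 1, 2)),
    edges = edges,
    myofibrils = if (n_myofibrils) lapply(seq_len(n_myofibrils),
                                          function(i) c(1L, 2L, 3L)) else
      list(),
    n_sarcomeres_before_extension = n,
    config = sarc_config()
  ), class = "sarc_detection")
}
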