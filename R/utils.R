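# Internal geometry and validation helpers. All public coordinates are
# (row, col), 0-based, sub-pixel; conversion to 1-based matrix indices
# happens only at pixel access.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(image)))
    stop("`image` contains non-finite pixel values", call. = FALSE)
  invisible(image)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

round_half_up <- function(x) floor(x + 0.5)

# Shoelace area of a closed polygon given as an n x 2 matrix of vertices
# (last vertex not repeated).
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 2]; y <- v[, 1]
  j <- c(n, seq_len(n - 1))
  unname(abs(sum(x[j] * y - x * y[j])) / 2)
}

polygon_perimeter <- function(v, closed = TRUE) {
  n <- nrow(v)
  if (n < 2) return(0)
  d <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  p <- sum(d)
  if (closed) p <- p + sqrt((v[1, 1] - v[n, 1])^2 + (v[1, 2] - v[n, 2])^2)
  unname(p)
}

# Even-odd point-in-polygon test, vectorized over query points.
# pts, poly: (row, col) matrices; polygon closed implicitly.
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  px <- pts[, 2]; py <- pts[, 1]
  inside <- logical(length(px))
  xj <- poly[n, 2]; yj <- poly[n, 1]
  for (i in seq_len(n)) {
    xi <- poly[i, 2]; yi <- poly[i, 1]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi; yj <- yi
  }
  inside
}

# Integer pixel centers (0-based) inside a contour polygon, restricted to
# the image frame. Returns an m x 2 matrix of (row, col).
contour_interior_pixels <- function(contour, nr, nc) {
  v <- contour$vertices
  r0 <- max(0L, floor(min(v[, 1])))
  r1 <- min(nr - 1L, ceiling(max(v[, 1])))
  c0 <- max(0L, floor(min(v[, 2])))
  c1 <- min(nc - 1L, ceiling(max(v[, 2])))
  if (r1 < r0 || c1 < c0) return(matrix(numeric(0), 0, 2))
  grid <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  grid[points_in_polygon(grid, v), , drop = FALSE]
}

# Angle of the vector (dr, dc) folded into [0, pi) -- orientation of an
# undirected segment.
segment_orientation <- function(dr, dc) {
  th <- atan2(dr, dc)
  th <- th %% pi
  ifelse(th >= pi, th - pi, th)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))
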