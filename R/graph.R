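# The sarcomere graph: z-discs are nodes, candidate sarcomeres are edges
# of a mutual k-nearest-neighbor graph. Four scoring methods grade each
# edge; probabilistic ensemble averaging fuses them into one probability.

#' Scoring configuration for the sarcomere graph
#'
#' @param c1,c2,c3 weights of the angular, length-consistency, and
#'   length-prior terms of the original edge score; must sum to 1
#'   (defaults 1/3 each).
#' @param l_min,l_max acceptable sarcomere length range in pixels
#'   (defaults 10 and 20; an edge outside `(l_min, l_max)` scores 0).
#' @param l_avg prior average sarcomere length in pixels (default 15).
#' @param N_neighbors neighbor count of the mutual kNN graph (default 4:
#'   the two chain partners plus lateral or crossing contacts; in dense
#'   parallel-myofibril fields a z-disc's nearest neighbors often include
#'   z-discs of adjacent myofibrils, so the candidate list must be deep
#'   enough to retain both chain partners).
#' @param pi0 prior probability that an edge is a sarcomere (0.5 = no
#'   preference).
#' @param epsilon_clip scores are clipped to
#'   `[epsilon_clip, 1 - epsilon_clip]` before the ensemble product so a
#'   single hard 0 cannot annihilate it.
#' @param T_alignment iteration count of the global-alignment recursion.
#' @param s_accept,s_strong pruning thresholds: accepted edges need a
#'   score of at least `s_accept`; accepted edges scoring at least
#'   `s_strong` are "strongly valid".
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(c1 = 1 / 3, c2 = 1 / 3, c3 = 1 / 3,
                           l_min = 10, l_max = 20, l_avg = 15,
                           N_neighbors = 4, pi0 = 0.5,
                           epsilon_clip = 0.01, T_alignment = 5,
                           s_accept = 0.5, s_strong = 0.75) {
  if (abs(c1 + c2 + c3 - 1) > 1e-9)
    stop("c1 + c2 + c3 must equal 1", call. = FALSE)
  if (!(l_min > 0 && l_min < l_avg && l_avg < l_max))
    stop("need 0 < l_min < l_avg < l_max", call. = FALSE)
  if (pi0 <= 0 || pi0 >= 1) stop("`pi0` must be in (0, 1)", call. = FALSE)
  if (epsilon_clip <= 0 || epsilon_clip >= 0.5)
    stop("`epsilon_clip` must be in (0, 0.5)", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, c3 = c3, l_min = l_min, l_max = l_max,
                 l_avg = l_avg, N_neighbors = as.integer(N_neighbors),
                 pi0 = pi0, epsilon_clip = epsilon_clip,
                 T_alignment = as.integer(T_alignment),
                 s_accept = s_accept, s_strong = s_strong),
            class = "scoring_config")
}

#' Build the mutual k-nearest-neighbor z-disc graph
#'
#' An edge joins z-discs a and b iff b is among a's `N_neighbors` nearest
#' neighbors *and* a is among b's (Euclidean distance).
#'
#' @param zdiscs data.frame with columns `row`, `col`, `p_zdisc` (one row
#'   per z-disc; row order defines node ids).
#' @param N_neighbors neighbor count.
#' @return A `sarc_graph`: list with `nodes` (the z-disc data.frame) and
#'   `edges` (data.frame `a`, `b`, `length`, `orientation` with `a < b`).
#' @export
build_candidate_graph <- function(zdiscs, N_neighbors = 4) {
  n <- nrow(zdiscs)
  edges <- data.frame(a = integer(0), b = integer(0), length = numeric(0),
                      orientation = numeric(0))
  if (n < 2) {
    warning("fewer than 2 z-discs; returning an empty graph")
    return(structure(list(nodes = zdiscs, edges = edges),
                     class = "sarc_graph"))
  }
  D <- as.matrix(dist(zdiscs[, c("row", "col")]))
  diag(D) <- Inf
  k <- min(N_neighbors, n - 1)
  nn <- apply(D, 1, function(d) order(d)[seq_len(k)], simplify = FALSE)
  a_idx <- integer(0); b_idx <- integer(0)
  for (i in seq_len(n)) {
    for (j in nn[[i]]) {
      if (j > i && i %in% nn[[j]]) {
        a_idx <- c(a_idx, i); b_idx <- c(b_idx, j)
      }
    }
  }
  if (length(a_idx)) {
    dr <- zdiscs$row[b_idx] - zdiscs$row[a_idx]
    dc <- zdiscs$col[b_idx] - zdiscs$col[a_idx]
    edges <- data.frame(a = a_idx, b = b_idx,
                        length = sqrt(dr^2 + dc^2),
                        orientation = segment_orientation(dr, dc))
  }
  structure(list(nodes = zdiscs, edges = edges), class = "sarc_graph")
}

#' @export
print.sarc_graph <- function(x, ...) {
  cat("Sarcomere candidate graph: ", nrow(x$nodes), " z-discs, ",
      nrow(x$edges), " candidate edges\n", sep = "")
  invisible(x)
}

#' Angle between two edges at their shared node
#'
#' Defined so that a perfectly collinear continuation scores 0 and
#' doubling back scores pi: theta = pi - angle between the two edge
#' vectors pointing away from the shared node.
#'
#' @param edge_i,edge_j length-2 integer vectors of node ids.
#' @param nodes data.frame with `row`, `col` positions indexed by node id.
#' @return Angle in `[0, pi]`.
#' @export
neighbor_angle <- function(edge_i, edge_j, nodes) {
  shared <- intersect(edge_i, edge_j)
  if (length(shared) != 1)
    stop("edges must share exactly one node", call. = FALSE)
  fi <- setdiff(edge_i, shared); fj <- setdiff(edge_j, shared)
  p0 <- c(nodes$row[shared], nodes$col[shared])
  u <- c(nodes$row[fi], nodes$col[fi]) - p0
  v <- c(nodes$row[fj], nodes$col[fj]) - p0
  ca <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  pi - acos(clamp(ca, -1, 1))
}

# f1: angular alignment, 1 at collinear continuation, 0 beyond pi/2.
f_angle <- function(theta) ifelse(theta <= pi / 2, (1 - theta / (pi / 2))^2, 0)
# f2: length consistency of edge i relative to neighbor j.
f_length_consistency <- function(l_i, l_j) 1 / (1 + abs(l_j - l_i) / l_i)
# f3: closeness of the edge length to the prior average.
f_length_prior <- function(l_i, l_avg) exp(-pi * (1 - l_i / l_avg)^2)

# For each edge and each of its two endpoints, the indices of the other
# edges incident to that endpoint, plus the pairwise angle and the far-end
# side of the neighbor. Shared by score_original and score_global_alignment.
edge_adjacency <- function(graph) {
  E <- graph$edges
  nE <- nrow(E)
  incident <- split(rep(seq_len(nE), 2), c(E$a, E$b))
  adj <- vector("list", nE)
  for (e in seq_len(nE)) {
    per_side <- vector("list", 2)
    for (side in 1:2) {
      node <- if (side == 1) E$a[e] else E$b[e]
      nbrs <- setdiff(incident[[as.character(node)]] %||% integer(0), e)
      if (length(nbrs)) {
        theta <- vapply(nbrs, function(e2)
          neighbor_angle(c(E$a[e], E$b[e]), c(E$a[e2], E$b[e2]),
                         graph$nodes), numeric(1))
        far_side <- vapply(nbrs, function(e2)
          if (E$a[e2] == node) 2L else 1L, integer(1))
        per_side[[side]] <- list(edges = nbrs, theta = theta,
                                 far_side = far_side)
      } else {
        per_side[[side]] <- list(edges = integer(0), theta = numeric(0),
                                 far_side = integer(0))
      }
    }
    adj[[e]] <- per_side
  }
  adj
}

#' Original local edge score
#'
#' For each edge i with length inside `(l_min, l_max)`:
#' `S_i = max_j (c1 f1(theta_ij) + c2 f2(l_i, l_j)) + c3 f3(l_i)`, the max
#' running over all edges j incident to either endpoint of i; an edge with
#' no neighbors keeps only the `c3` term. Edges with length outside the
#' range score 0. Results are clipped to [0, 1].
#'
#' @param graph a `sarc_graph`.
#' @param config a [scoring_config()].
#' @param adjacency optional precomputed [edge_adjacency()] result.
#' @return Numeric vector of per-edge scores.
#' @export
score_original <- function(graph, config = scoring_config(),
                           adjacency = NULL) {
  E <- graph$edges
  nE <- nrow(E)
  if (nE == 0) return(numeric(0))
  if (is.null(adjacency)) adjacency <- edge_adjacency(graph)
  s <- numeric(nE)
  for (e in seq_len(nE)) {
    l_i <- E$length[e]
    if (!(l_i > config$l_min && l_i < config$l_max)) next
    best <- -Inf
    for (side in 1:2) {
      nb <- adjacency[[e]][[side]]
      if (length(nb$edges) == 0) next
      vals <- config$c1 * f_angle(nb$theta) +
        config$c2 * f_length_consistency(l_i, E$length[nb$edges])
      best <- max(best, vals)
    }
    if (!is.finite(best)) best <- 0   # isolated edge: only the c3 term
    s[e] <- best + config$c3 * f_length_prior(l_i, config$l_avg)
  }
  clamp(s, 0, 1)
}

#' Z-disc probability edge score
#'
#' The mean of the two endpoint z-disc probabilities.
#'
#' @inheritParams score_original
#' @return Numeric vector of per-edge scores.
#' @export
score_zdisc_probability <- function(graph) {
  E <- graph$edges
  (graph$nodes$p_zdisc[E$a] + graph$nodes$p_zdisc[E$b]) / 2
}

#' Pruning-based validity edge score
#'
#' Runs the pruning pass on the original-score graph and maps the
#' resulting validity classes (0 rejected, 1 weakly valid, 2 strongly
#' valid) to scores `epsilon_clip`, 0.5, and `1 - epsilon_clip`. This
#' injects the original pipeline's accept/reject decision into the
#' ensemble as one vote.
#'
#' @inheritParams score_original
#' @param s_original optional precomputed [score_original()] vector.
#' @return Numeric vector of per-edge scores.
#' @export
score_pruning_validity <- function(graph, config = scoring_config(),
                                   s_original = NULL, adjacency = NULL) {
  if (is.null(s_original))
    s_original <- score_original(graph, config, adjacency)
  pr <- prune_graph(graph, s_original, s_accept = config$s_accept,
                    s_strong = config$s_strong)
  c(config$epsilon_clip, 0.5, 1 - config$epsilon_clip)[pr$validity + 1L]
}

#' Global myofibril alignment edge score
#'
#' Measures an edge's potential to sit inside a long, coherent myofibril
#' by iteratively propagating "reach" between neighboring edges. With
#' `R^0 = 0` at both ends of every edge, each iteration updates
#' `R^t(end) = max over continuing edges e' at that end of
#' f1(theta) * f2(l_e, l_e') * (1 + R^{t-1}(far end of e'))`, and the
#' score is `(R^T(left) + R^T(right)) / (2 T)`, clipped to [0, 1]. An
#' interior edge of a straight, evenly spaced chain of length >= T
#' saturates at 1; an isolated edge scores 0.
#'
#' @inheritParams score_original
#' @return Numeric vector of per-edge scores.
#' @export
score_global_alignment <- function(graph, config = scoring_config(),
                                   adjacency = NULL) {
  E <- graph$edges
  nE <- nrow(E)
  if (nE == 0) return(numeric(0))
  if (is.null(adjacency)) adjacency <- edge_adjacency(graph)
  R <- matrix(0, nE, 2)
  for (t in seq_len(config$T_alignment)) {
    R_new <- matrix(0, nE, 2)
    for (e in seq_len(nE)) {
      for (side in 1:2) {
        nb <- adjacency[[e]][[side]]
        if (length(nb$edges) == 0) next
        w <- f_angle(nb$theta) *
          f_length_consistency(E$length[e], E$length[nb$edges])
        R_new[e, side] <- max(w * (1 + R[cbind(nb$edges, nb$far_side)]))
      }
    }
    R <- R_new
  }
  clamp((R[, 1] + R[, 2]) / (2 * config$T_alignment), 0, 1)
}

#' Probabilistic ensemble averaging of edge scores
#'
#' Fuses n per-edge scores into one posterior probability. With a prior
#' `pi0`, the sarcomere likelihood is proportional to
#' `prod(s_i) / pi0^(n-1)` and the complement to
#' `prod(1 - s_i) / (1 - pi0)^(n-1)`; normalizing gives the posterior.
#' For `pi0 = 0.5` this reduces to
#' `p = prod(s) / (prod(s) + prod(1 - s))`. Scores are clipped to
#' `[epsilon_clip, 1 - epsilon_clip]` first so no single method can
#' zero out the product.
#'
#' @param scores numeric matrix (edges x methods) or vector (one edge per
#'   entry, single method).
#' @param config a [scoring_config()] (supplies `pi0` and `epsilon_clip`).
#' @return Numeric vector of posterior probabilities, one per edge.
#' @export
ensemble_scores <- function(scores, config = scoring_config()) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  if (nrow(scores) == 0) return(numeric(0))
  s <- clamp(scores, config$epsilon_clip, 1 - config$epsilon_clip)
  n <- ncol(s)
  # clipping bounds the products away from 0, so the plain products are
  # numerically safe for any realistic number of methods
  num <- apply(s, 1, prod) / config$pi0^(n - 1)
  den <- apply(1 - s, 1, prod) / (1 - config$pi0)^(n - 1)
  num / (num + den)
}

#' Prune the scored graph
#'
#' Greedy acceptance in order of decreasing score: an edge is accepted iff
#' both endpoints currently have fewer than 2 accepted edges and its score
#' is at least `s_accept`. Accepted edges scoring at least `s_strong` get
#' validity class 2 (strongly valid), other accepted edges class 1, all
#' remaining edges class 0 (rejected). The degree cap encodes that a
#' z-disc joins at most two sarcomeres along a myofibril.
#'
#' @param graph a `sarc_graph`.
#' @param edge_scores numeric vector of per-edge scores in [0, 1].
#' @param s_accept,s_strong acceptance and strong-validity thresholds.
#' @return List with `validity` (integer vector in \{0, 1, 2\}) and
#'   `retained` (logical vector, validity > 0).
#' @export
prune_graph <- function(graph, edge_scores, s_accept = 0.5,
                        s_strong = 0.75) {
  E <- graph$edges
  nE <- nrow(E)
  validity <- integer(nE)
  if (nE > 0) {
    deg <- integer(max(c(E$a, E$b)))
    for (e in order(-edge_scores, seq_len(nE))) {
      if (edge_scores[e] < s_accept) next
      if (deg[E$a[e]] >= 2 || deg[E$b[e]] >= 2) next
      validity[e] <- if (edge_scores[e] >= s_strong) 2L else 1L
      deg[E$a[e]] <- deg[E$a[e]] + 1L
      deg[E$b[e]] <- deg[E$b[e]] + 1L
    }
  }
  list(validity = validity, retained = validity > 0L)
}
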