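# Myofibril assembly from the pruned graph, gap-bridging extension with
# virtual z-discs, and singleton removal.

#' Assemble myofibrils from the pruned graph
#'
#' After pruning, every node has degree at most 2, so each connected
#' component is a simple path or a cycle. Cycles are broken at their
#' lowest-score edge. Each remaining path with at least one edge becomes a
#' myofibril: an ordered chain of z-disc ids.
#'
#' @param graph a `sarc_graph`.
#' @param retained logical vector marking the edges kept by
#'   [prune_graph()].
#' @param edge_scores per-edge scores (used to break cycles).
#' @return List of integer vectors; each is an ordered chain of node ids.
#' @export
assemble_myofibrils <- function(graph, retained, edge_scores) {
  E <- graph$edges[retained, , drop = FALSE]
  sc <- edge_scores[retained]
  if (nrow(E) == 0) return(list())
  nodes <- sort(unique(c(E$a, E$b)))
  deg <- table(factor(c(E$a, E$b), levels = nodes))
  if (any(deg > 2))
    stop("internal error: node degree > 2 after pruning", call. = FALSE)
  n_edge <- nrow(E)
  edge_of <- split(rep(seq_len(n_edge), 2), c(E$a, E$b))
  visited <- logical(n_edge)
  chains <- list()

  walk_from <- function(start_node, start_edge) {
    chain <- start_node
    node <- start_node
    e <- start_edge
    repeat {
      visited[e] <<- TRUE
      node <- if (E$a[e] == node) E$b[e] else E$a[e]
      chain <- c(chain, node)
      nxt <- setdiff(edge_of[[as.character(node)]], which(visited))
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0) break
      e <- nxt[1]
    }
    chain
  }

  # paths: start at degree-1 endpoints
  endpoints <- as.integer(names(deg)[deg == 1])
  for (v in endpoints) {
    e0 <- edge_of[[as.character(v)]]
    e0 <- e0[!visited[e0]]
    if (length(e0) == 0) next
    chains[[length(chains) + 1L]] <- walk_from(v, e0[1])
  }
  # cycles: any unvisited edges form pure cycles; break each at its
  # weakest edge
  while (any(!visited)) {
    weak <- which(!visited)[which.min(sc[!visited])]
    visited[weak] <- TRUE
    comp_start <- E$a[weak]
    e0 <- edge_of[[as.character(comp_start)]]
    e0 <- e0[!visited[e0]]
    if (length(e0) == 0) { # single-edge cycle cannot happen; guard anyway
      next
    }
    chains[[length(chains) + 1L]] <- walk_from(comp_start, e0[1])
  }
  chains
}

ext_defaults <- function() {
  list(match_radius = 7, length_bounds = c(10, 20), max_turn_deg = 22.5,
       p_min = 0.5, max_iterations = 3)
}

turn_angle_deg <- function(v_prev, v_new) {
  ca <- sum(v_prev * v_new) /
    (sqrt(sum(v_prev^2)) * sqrt(sum(v_new^2)) + 1e-300)
  acos(clamp(ca, -1, 1)) * 180 / pi
}

#' Extend myofibrils across detection gaps
#'
#' Each myofibril end projects a virtual z-disc by translating its
#' terminal z-disc by the terminal sarcomere's length along its direction.
#' A projection is appended when it matches (within `match_radius` px)
#' either a real z-disc with probability above `p_min` (possibly one
#' already belonging to another myofibril, as happens where two
#' myofibrils cross), or the projection of another myofibril's end. When
#' two ends' projections meet, the fragments are merged through a shared
#' virtual z-disc at the midpoint of the two projections; when an end's
#' projection lands on another fragment's terminal z-disc and vice versa,
#' the fragments are joined directly. In every case the new sarcomere
#' must have length within `length_bounds` and turn less than
#' `max_turn_deg` degrees relative to the terminal sarcomere, and may not
#' duplicate a sarcomere that already exists in some myofibril. The
#' process repeats up to `max_iterations` times. Appended nodes with no
#' matching real z-disc are flagged `is_virtual`.
#'
#' @param myofibrils list of node-id chains from [assemble_myofibrils()].
#' @param zdiscs data.frame of all detected z-discs (`row`, `col`,
#'   `p_zdisc`, `is_virtual`); node ids are row indices.
#' @param match_radius,length_bounds,max_turn_deg,p_min,max_iterations
#'   extension rules: 7 px match radius, new sarcomere length in
#'   [10, 20] px, turn < 22.5 degrees, real-match probability > 0.5, and
#'   up to 3 passes, by default.
#' @return List with `myofibrils` (updated chains) and `zdiscs` (possibly
#'   augmented with virtual nodes).
#' @export
extend_myofibrils <- function(myofibrils, zdiscs,
                              match_radius = 7,
                              length_bounds = c(10, 20),
                              max_turn_deg = 22.5,
                              p_min = 0.5,
                              max_iterations = 3) {
  if (length(myofibrils) == 0)
    return(list(myofibrils = myofibrils, zdiscs = zdiscs))
  pos <- function(id) c(zdiscs$row[id], zdiscs$col[id])
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  existing_edges <- function() {
    unlist(lapply(myofibrils, function(ch) {
      if (length(ch) < 2) return(character(0))
      vapply(seq_len(length(ch) - 1), function(i)
        edge_key(ch[i], ch[i + 1]), character(1))
    }))
  }

  for (iter in seq_len(max_iterations)) {
    changed <- FALSE

    # collect ends: myofibril index, side (1 head / 2 tail), terminal and
    # previous node, projection
    ends <- list()
    for (m in seq_along(myofibrils)) {
      ch <- myofibrils[[m]]
      if (length(ch) < 2) next
      for (side in 1:2) {
        t_id <- if (side == 1) ch[1] else ch[length(ch)]
        q_id <- if (side == 1) ch[2] else ch[length(ch) - 1]
        v_dir <- pos(t_id) - pos(q_id)
        ends[[length(ends) + 1L]] <- list(
          m = m, side = side, t_id = t_id, q_id = q_id,
          proj = pos(t_id) + v_dir, dir = v_dir)
      }
    }
    if (length(ends) == 0) break
    alive <- rep(TRUE, length(ends))
    mf_alive <- rep(TRUE, length(myofibrils))
    edge_set <- existing_edges()

    ok_new_sarc <- function(end, target) {
      len <- euclid(pos(end$t_id), target)
      if (len < length_bounds[1] || len > length_bounds[2]) return(FALSE)
      turn_angle_deg(end$dir, target - pos(end$t_id)) < max_turn_deg
    }
    kill_myofibril_ends <- function(ms) {
      alive[vapply(ends, function(e) e$m %in% ms, logical(1))] <<- FALSE
    }
    merge_chains <- function(ei, ej, bridge_ids) {
      ci <- myofibrils[[ei$m]]; cj <- myofibrils[[ej$m]]
      if (ei$side == 1) ci <- rev(ci)
      if (ej$side == 2) cj <- rev(cj)
      myofibrils[[ei$m]] <<- c(ci, bridge_ids, cj)
      myofibrils[[ej$m]] <<- integer(0)
      mf_alive[ej$m] <<- FALSE
      kill_myofibril_ends(c(ei$m, ej$m))
      changed <<- TRUE
    }

    # phase 1: two projections meet -> merge through a shared z-disc at
    # the midpoint (a real one if a high-probability z-disc sits there,
    # otherwise a new virtual node); closest pairs first
    if (length(ends) >= 2) {
      pairs <- NULL
      for (i in seq_along(ends)) for (j in seq_along(ends)) {
        if (j <= i) next
        if (ends[[i]]$m == ends[[j]]$m) next
        d <- euclid(ends[[i]]$proj, ends[[j]]$proj)
        if (d <= match_radius) pairs <- rbind(pairs, c(i, j, d))
      }
      if (!is.null(pairs)) {
        for (r in order(pairs[, 3])) {
          i <- pairs[r, 1]; j <- pairs[r, 2]
          ei <- ends[[i]]; ej <- ends[[j]]
          if (!alive[i] || !alive[j]) next
          if (!mf_alive[ei$m] || !mf_alive[ej$m]) next
          mid <- (ei$proj + ej$proj) / 2
          if (!ok_new_sarc(ei, mid) || !ok_new_sarc(ej, mid)) next
          # prefer a real high-probability z-disc at the meeting point
          free <- which(zdiscs$p_zdisc > p_min & !zdiscs$is_virtual)
          free <- setdiff(free, c(myofibrils[[ei$m]], myofibrils[[ej$m]]))
          real_id <- NA_integer_
          if (length(free)) {
            d_real <- sqrt((zdiscs$row[free] - mid[1])^2 +
                             (zdiscs$col[free] - mid[2])^2)
            if (min(d_real) <= match_radius) {
              cand <- free[which.min(d_real)]
              if (ok_new_sarc(ei, pos(cand)) && ok_new_sarc(ej, pos(cand)))
                real_id <- cand
            }
          }
          if (is.na(real_id)) {
            zdiscs <- rbind(zdiscs, data.frame(
              row = mid[1], col = mid[2], p_zdisc = p_min,
              parent_contour_id = NA_integer_, is_secondary = FALSE,
              is_virtual = TRUE, peak_intensity = NA_real_))
            new_id <- nrow(zdiscs)
          } else new_id <- real_id
          merge_chains(ei, ej, new_id)
        }
      }
    }

    # phase 2: facing ends -- each projection lands on the other
    # fragment's terminal z-disc -> join the fragments directly
    if (length(ends) >= 2) {
      for (i in seq_along(ends)) for (j in seq_along(ends)) {
        if (j <= i) next
        ei <- ends[[i]]; ej <- ends[[j]]
        if (!alive[i] || !alive[j]) next
        if (ei$m == ej$m) next
        if (!mf_alive[ei$m] || !mf_alive[ej$m]) next
        if (euclid(ei$proj, pos(ej$t_id)) > match_radius) next
        if (euclid(ej$proj, pos(ei$t_id)) > match_radius) next
        if (edge_key(ei$t_id, ej$t_id) %in% edge_set) next
        if (!ok_new_sarc(ei, pos(ej$t_id)) ||
              !ok_new_sarc(ej, pos(ei$t_id))) next
        edge_set <- c(edge_set, edge_key(ei$t_id, ej$t_id))
        merge_chains(ei, ej, integer(0))
      }
    }

    # phase 3: match remaining projections to real z-discs (possibly in
    # another myofibril, as at crossings), without duplicating an
    # existing sarcomere
    for (i in seq_along(ends)) {
      if (!alive[i]) next
      e <- ends[[i]]
      if (!mf_alive[e$m]) next
      free <- which(zdiscs$p_zdisc > p_min & !zdiscs$is_virtual)
      free <- setdiff(free, myofibrils[[e$m]])
      if (length(free) == 0) next
      d <- sqrt((zdiscs$row[free] - e$proj[1])^2 +
                  (zdiscs$col[free] - e$proj[2])^2)
      ord <- order(d)
      for (k in ord) {
        if (d[k] > match_radius) break
        cand <- free[k]
        if (edge_key(e$t_id, cand) %in% edge_set) next
        if (!ok_new_sarc(e, pos(cand))) next
        ch <- myofibrils[[e$m]]
        myofibrils[[e$m]] <- if (e$side == 1) c(cand, ch) else c(ch, cand)
        edge_set <- c(edge_set, edge_key(e$t_id, cand))
        alive[i] <- FALSE
        changed <- TRUE
        break
      }
    }

    myofibrils <- myofibrils[mf_alive & lengths(myofibrils) > 0]
    if (!changed) break
  }
  list(myofibrils = myofibrils, zdiscs = zdiscs)
}

#' Remove single-sarcomere myofibrils
#'
#' Keeps only myofibrils containing at least two sarcomeres (three
#' z-discs).
#'
#' @param myofibrils list of node-id chains.
#' @return Filtered list.
#' @export
drop_singletons <- function(myofibrils) {
  myofibrils[lengths(myofibrils) >= 3]
}
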