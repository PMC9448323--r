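#' Graphical interpolation of missing nuclei
#'
#' Nuclei whose gates contained no detection are placed at their previous
#' position plus the mean displacement of their assigned graph neighbors;
#' when every direct neighbor is also missing, the nearest assigned
#' neighborhood (expanding graph-distance rings) is used instead.
#'
#' @param positions Numeric matrix like `previous$positions` whose rows for
#'   MISSING nuclei are `NA`; assigned rows hold the accepted detection
#'   coordinates.
#' @param previous The previous [posture_state()].
#' @param graph An [build_embryo_graph()] over the same nodes.
#' @return A complete [posture_state()] with `interpolated` set.
#' @export
interpolate_missing <- function(positions, previous, graph) {
  positions <- as.matrix(positions)
  ids <- rownames(previous$positions)
  stopifnot(identical(rownames(positions), ids))
  assigned <- stats::complete.cases(positions)
  if (!any(assigned)) stop("cannot interpolate: zero assigned nuclei")
  nbrs <- graph_neighbors(graph)
  disp <- positions - previous$positions
  out <- positions
  for (i in which(!assigned)) {
    ring <- ids[i]
    seen <- ids[i]
    donors <- character()
    while (length(ring) && !length(donors)) {
      nxt <- setdiff(unique(unlist(nbrs[ring], use.names = FALSE)), seen)
      donors <- nxt[assigned[match(nxt, ids)]]
      seen <- c(seen, nxt)
      ring <- nxt
    }
    if (!length(donors)) {
      out[i, ] <- previous$positions[i, ]
    } else {
      d <- colMeans(disp[donors, , drop = FALSE])
      out[i, ] <- previous$positions[i, ] + d
    }
  }
  posture_state(out, frame = previous$frame + 1L,
                time_s = NULL, frame_rate = 3,
                interpolated = ids[!assigned])
}

segment_segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) { s <- 0; t <- 0 }
  else if (a <= eps) { s <- 0; t <- min(1, max(0, f / e)) }
  else {
    cc <- sum(d1 * r)
    if (e <= eps) { t <- 0; s <- min(1, max(0, -cc / a)) }
    else {
      b <- sum(d1 * d2); denom <- a * e - b * b
      s <- if (denom > eps) min(1, max(0, (b * f - cc * e) / denom)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(1, max(0, -cc / a)) }
      else if (t > 1) { t <- 1; s <- min(1, max(0, (b - cc) / a)) }
    }
  }
  sqrt(sum(((p1 + s * d1) - (p2 + t * d2))^2))
}

#' Detect physically impossible self-intersecting postures
#'
#' The body midline is approximated by the midpoints of the ten left/right
#' lateral pairs joined in rank order (9 segments). The posture
#' self-intersects when any two non-adjacent midline segments approach
#' closer than `min_separation_um` (strict inequality: exactly
#' `min_separation_um` apart is allowed).
#'
#' @param state A complete 20-nucleus [posture_state()].
#' @param min_separation_um Minimum allowed distance between non-adjacent
#'   midline segments (um).
#' @return Logical.
#' @export
self_intersects <- function(state, min_separation_um = 2) {
  if (!is_full_embryo_state(state))
    stop("self_intersects requires a full 20-nucleus embryo state")
  tab <- seam_cell_table()
  left <- tab$id[tab$side == "L"][order(tab$rank[tab$side == "L"])]
  right <- tab$id[tab$side == "R"][order(tab$rank[tab$side == "R"])]
  mid <- (state$positions[left, , drop = FALSE] +
            state$positions[right, , drop = FALSE]) / 2
  ns <- nrow(mid) - 1L
  for (i in seq_len(ns - 2L)) {
    for (j in seq.int(i + 2L, ns)) {
      d <- segment_segment_distance(mid[i, ], mid[i + 1L, ], mid[j, ], mid[j + 1L, ])
      if (d < min_separation_um) return(TRUE)
    }
  }
  FALSE
}

midline_pair_rows <- function(ids) {
  tab <- seam_cell_table()
  left <- tab$id[tab$side == "L"][order(tab$rank[tab$side == "L"])]
  right <- tab$id[tab$side == "R"][order(tab$rank[tab$side == "R"])]
  cbind(match(left, ids), match(right, ids)) - 1L
}

cost_model_code <- function(model) {
  match(model, c("gnn", "embryo", "posture", "movement", "pm")) - 1L
}

#' Track nuclei with multiple-hypothesis hypergraph tracking
#'
#' From a manually seeded posture, the tracker advances frame by frame. At
#' each frame it expands a K-ary hypothesis tree over the next N frames:
#' every surviving node is expanded into its K best gated assignments
#' (Murty's algorithm on the gated GNN problem), missing nuclei are
#' graphically interpolated, self-intersecting hypotheses are pruned, and
#' each path is scored by the summed per-step cost of the configured model
#' (the GNN model scores by the gated association cost itself; Embryo and
#' Posture add that association cost as their unary term with weight
#' `config$unary_weight`; Movement and PM subsume positional differences and
#' add only the gate^2 penalty per missing nucleus). The frame-t assignment
#' of the minimum-summed-cost path is committed, the tree re-roots, and the
#' process repeats. With `K = 1, N = 1` the output is identical to the gated
#' GNN baseline. Frames whose committed step cost exceeds
#' `config$flag_threshold` are flagged for manual review.
#'
#' @param detections List of per-frame detection matrices (m x 3, um), or a
#'   `detection_sequence`.
#' @param seed_state The complete [posture_state()] at the frame preceding
#'   the first detection set.
#' @param model A `covariance_model` (required for the posture, movement and
#'   pm cost models; ignored otherwise).
#' @param graph An [build_embryo_graph()].
#' @param config A [tracking_config()].
#' @return List of class `mhht_tracks`: `states` (a `posture_sequence`),
#'   `assignment` (frame x nucleus detection indices, `NA` = missing),
#'   `interpolated`, `step_cost` (the committed per-step objective),
#'   `assoc_cost` (gated association cost) and `flagged` per frame.
#' @export
track_mhht <- function(detections, seed_state, model = NULL,
                       graph = build_embryo_graph(), config = tracking_config()) {
  if (is.list(detections) && !is.null(detections$detections))
    detections <- detections$detections
  if (!length(detections)) stop("empty detection sequence")
  detections <- lapply(detections, function(d) {
    d <- if (is.list(d) && !is.null(d$points)) d$points else as.matrix(d)
    if (length(d) == 0L) d <- matrix(numeric(), 0L, 3L)
    storage.mode(d) <- "double"
    d
  })
  ids <- rownames(seed_state$positions)
  code <- cost_model_code(config$cost_model)
  needs_P <- config$cost_model %in% c("posture", "pm")
  needs_M <- config$cost_model %in% c("movement", "pm")
  if ((needs_P || needs_M) && is.null(model))
    stop("cost model '", config$cost_model, "' requires a covariance_model")
  sPi <- if (needs_P) model$sigma_P_inv else matrix(0, 0L, 0L)
  sMi <- if (needs_M) model$sigma_M_inv else matrix(0, 0L, 0L)
  edge_idx <- cbind(match(graph$edges$from, ids), match(graph$edges$to, ids)) - 1L
  mid <- if (length(ids) == 20L && all(ids == seam_cell_ids()))
    midline_pair_rows(ids) else matrix(integer(), 0L, 2L)
  res <- .track_mhht_cpp(detections, seed_state$positions, edge_idx,
                         sPi, sMi, mid,
                         config$K, config$N, config$gate_radius_um, code,
                         config$unary_weight, config$min_separation_um,
                         isTRUE(config$prune_self_intersections))
  TT <- length(detections)
  states <- vector("list", TT)
  for (t in seq_len(TT)) {
    pos <- matrix(res$positions[t, ], ncol = 3L, byrow = TRUE,
                  dimnames = list(ids, c("x", "y", "z")))
    states[[t]] <- posture_state(pos, frame = seed_state$frame + t,
                                 interpolated = ids[res$interpolated[t, ]])
  }
  flagged <- if (is.null(config$flag_threshold)) rep(FALSE, TT)
             else res$model_cost > config$flag_threshold
  assignment <- res$assignment
  dimnames(assignment) <- list(NULL, ids)
  structure(list(states = posture_sequence(states),
                 assignment = assignment,
                 interpolated = res$interpolated,
                 step_cost = as.numeric(res$model_cost),
                 assoc_cost = as.numeric(res$assoc_cost),
                 flagged = flagged, config = config),
            class = "mhht_tracks")
}

#' @export
print.mhht_tracks <- function(x, ...) {
  cat(sprintf("<mhht_tracks> %d frames, model '%s' (K=%d, N=%d), %d flagged\n",
              length(x$states), x$config$cost_model, x$config$K, x$config$N,
              sum(x$flagged)))
  invisible(x)
}

#' Posture error rate against ground truth
#'
#' A tracked volume counts as erroneous when any nucleus's committed
#' position maps to the wrong identity: its nearest true nucleus is a
#' different cell, it lies farther than `gate_um` from every true nucleus,
#' or (when a provenance map from [corrupt_detections()] is supplied) the
#' committed coordinates are those of a clutter detection.
#'
#' @param tracks An `mhht_tracks` object or a `posture_sequence`.
#' @param truth An `embryo_truth` (from [simulate_posture_sequence()]) or a
#'   `posture_sequence`, with the same frame count.
#' @param gate_um Distance beyond which a nucleus counts as lost.
#' @param provenance Optional per-frame provenance from
#'   [corrupt_detections()] (`$provenance`), used to detect clutter commits.
#' @param detections Optional detection list matching `provenance`.
#' @return List: `error_rate` (fraction of volumes with >= 1 misassigned
#'   nucleus), `frame_errors` (logical), `confusion` (per-cell counts of
#'   misassignments).
#' @export
evaluate_posture_error <- function(tracks, truth, gate_um = 6,
                                   provenance = NULL, detections = NULL) {
  states <- if (inherits(tracks, "mhht_tracks")) tracks$states else tracks
  truth_states <- if (inherits(truth, "embryo_truth")) truth$states else truth
  if (length(states) != length(truth_states))
    stop("tracks and truth must have the same number of frames")
  ids <- rownames(states[[1L]]$positions)
  confusion <- stats::setNames(integer(length(ids)), ids)
  frame_err <- logical(length(states))
  for (t in seq_along(states)) {
    P <- states[[t]]$positions[ids, , drop = FALSE]
    Q <- truth_states[[t]]$positions[ids, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
      outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
    nearest <- max.col(-d2, ties.method = "first")
    mind <- sqrt(pmax(d2[cbind(seq_along(nearest), nearest)], 0))
    bad <- nearest != seq_along(ids) | mind > gate_um
    if (!is.null(provenance) && !is.null(detections)) {
      det <- detections[[t]]
      pts <- if (is.list(det) && !is.null(det$points)) det$points else det
      if (nrow(pts)) {
        dd <- outer(rowSums(P^2), rep(1, nrow(pts))) +
          outer(rep(1, nrow(P)), rowSums(pts^2)) - 2 * P %*% t(pts)
        src <- max.col(-dd, ties.method = "first")
        exact <- sqrt(pmax(dd[cbind(seq_along(src), src)], 0)) < 1e-8
        lab <- provenance[[t]][src]
        bad <- bad | (exact & (lab == "CLUTTER" | (lab != ids & lab != "")))
      }
    }
    frame_err[t] <- any(bad)
    confusion[bad] <- confusion[bad] + 1L
  }
  list(error_rate = mean(frame_err), frame_errors = frame_err,
       confusion = confusion)
}

#' Detection quality against annotations
#'
#' One-to-one minimum-cost bipartite matching between detections and
#' annotated nucleus centers, with pairs farther apart than `max_dist_um`
#' forbidden.
#'
#' @param detections Matrix of detected 3D points, or a `detection_set`.
#' @param annotations Matrix of annotated 3D points.
#' @param max_dist_um Maximum allowed match distance (um).
#' @return List with `precision`, `recall`, `f1`, `n_matched` and the
#'   matching itself (`matches`: detection index, annotation index,
#'   distance).
#' @export
match_detections <- function(detections, annotations, max_dist_um) {
  stopifnot(max_dist_um > 0)
  pts <- if (is.list(detections) && !is.null(detections$points)) detections$points
         else as.matrix(detections)
  ann <- as.matrix(annotations)
  nd <- nrow(pts); na <- nrow(ann)
  if (nd == 0L || na == 0L) {
    return(list(precision = ifelse(nd == 0L, NA_real_, 0),
                recall = ifelse(na == 0L, NA_real_, 0), f1 = 0,
                n_matched = 0L,
                matches = data.frame(detection = integer(), annotation = integer(),
                                     distance = numeric())))
  }
  d <- sqrt(pmax(outer(rowSums(pts^2), rep(1, na)) +
                   outer(rep(1, nd), rowSums(ann^2)) - 2 * pts %*% t(ann), 0))
  cost <- matrix(1e12, nd, na + nd)
  ok <- d <= max_dist_um
  cost[, seq_len(na)][ok] <- d[ok]
  # dedicated dummy per detection: leaving it unmatched costs more than any
  # admissible match, so match cardinality is maximized first
  for (i in seq_len(nd)) cost[i, na + i] <- max_dist_um * 1000
  sol <- .lap_solve_cpp(cost)
  matched <- which(sol$assignment <= na)
  matches <- data.frame(detection = matched,
                        annotation = sol$assignment[matched],
                        distance = d[cbind(matched, sol$assignment[matched])])
  nm <- nrow(matches)
  precision <- nm / nd
  recall <- nm / na
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, n_matched = nm,
       matches = matches)
}
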