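#' Optimal linear assignment
#'
#' Solves the rectangular minimum-cost assignment problem (rows <= columns;
#' every row assigned to a distinct column) with a Hungarian algorithm using
#' dual potentials. Entries of `1e12` or more are treated as forbidden.
#'
#' @param cost Numeric cost matrix, `nrow(cost) <= ncol(cost)`.
#' @return List with `assignment` (column index per row), `cost` (total) and
#'   `feasible` (FALSE when only forbidden arcs could complete the solution).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (nrow(cost) > ncol(cost)) stop("cost matrix must have nrow <= ncol")
  if (any(!is.finite(cost))) stop("use large finite values (>= 1e12) for forbidden arcs")
  .lap_solve_cpp(cost)
}

#' Murty's ranked K-best assignments
#'
#' Enumerates the K cheapest complete assignments of a cost matrix in
#' non-decreasing cost order, by recursively partitioning the solution space
#' around each reported optimum and re-solving every subproblem with a
#' warm-started single augmenting path.
#'
#' @param cost Numeric cost matrix, `nrow <= ncol`.
#' @param K Number of ranked solutions requested (fewer are returned when
#'   the feasible set is smaller).
#' @return List of `list(assignment, cost)` in non-decreasing cost order.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6, 3, 6, 9), 3, 3)
#' murty_k_best(m, 3)
murty_k_best <- function(cost, K) {
  cost <- as.matrix(cost)
  if (nrow(cost) > ncol(cost)) stop("cost matrix must have nrow <= ncol")
  stopifnot(K >= 1)
  .murty_cpp(cost, as.integer(K))
}

#' Gated K-best data association
#'
#' Builds the gated linear data-association problem between a previous
#' posture and a detection set: the cost of assigning detection j to nucleus
#' i is their squared displacement; detections outside the nucleus's gate
#' are infeasible; every nucleus may instead be declared MISSING at cost
#' `gate_radius^2`; detections left unmatched are debris. The K
#' lowest-cost feasible assignments are returned in non-decreasing cost
#' order via Murty's algorithm. Exact ties are broken towards the lowest
#' detection index (and towards real detections over MISSING).
#'
#' @param previous A [posture_state()].
#' @param detections Numeric matrix of candidate 3D points (um), or a
#'   `detection_set` list with a `points` matrix.
#' @param config A [tracking_config()]; `config$K` and `config$gate_radius_um`
#'   are used.
#' @return List of assignments; each has `assignment` (named integer vector,
#'   detection index per nucleus, `NA` = MISSING), `cost` (squared
#'   displacements plus `gate^2` per missing nucleus) and `debris`
#'   (unmatched detection indices).
#' @export
gated_k_best_assignments <- function(previous, detections, config) {
  pts <- if (is.list(detections) && !is.null(detections$points)) detections$points
         else as.matrix(detections)
  if (length(pts) == 0L) pts <- matrix(numeric(), 0L, 3L)
  stopifnot(config$gate_radius_um > 0)
  sols <- .gated_murty_cpp(previous$positions, pts, config$gate_radius_um,
                           as.integer(config$K))
  ids <- rownames(previous$positions)
  lapply(sols, function(s) {
    a <- stats::setNames(s$assignment, ids)
    list(assignment = a, cost = s$cost,
         debris = setdiff(seq_len(nrow(pts)), a[!is.na(a)]))
  })
}

#' Tracking configuration
#'
#' @param K Hypothesis width: number of ranked assignments kept per
#'   expansion (>= 1).
#' @param N Lookahead depth in frames (>= 1). `K = 1, N = 1` reduces MHHT
#'   exactly to the gated GNN baseline.
#' @param gate_radius_um Gate radius around each nucleus's previous position
#'   (default 6 um at 3 Hz, about the largest credible inter-frame
#'   displacement).
#' @param cost_model One of `"gnn"`, `"embryo"`, `"posture"`, `"movement"`,
#'   `"pm"`.
#' @param flag_threshold Committed frames whose model cost exceeds this are
#'   flagged for manual review; `NULL` disables flagging.
#' @param unary_weight Weight of the GNN unary cost added to the Embryo and
#'   Posture models (the Movement and PM models already subsume positional
#'   differences).
#' @param min_separation_um Midline segments of a hypothesized posture
#'   closer than this are treated as a self-intersection and pruned.
#' @param prune_self_intersections Logical; pruning applies only to full
#'   20-nucleus embryo states.
#' @return A list of class `tracking_config`.
#' @export
tracking_config <- function(K = 5L, N = 5L, gate_radius_um = 6,
                            cost_model = c("pm", "gnn", "embryo", "posture", "movement"),
                            flag_threshold = NULL, unary_weight = 1,
                            min_separation_um = 2,
                            prune_self_intersections = TRUE) {
  cost_model <- match.arg(cost_model)
  stopifnot(K >= 1L, N >= 1L, K == as.integer(K), N == as.integer(N),
            gate_radius_um > 0, unary_weight >= 0, min_separation_um >= 0)
  structure(list(K = as.integer(K), N = as.integer(N),
                 gate_radius_um = gate_radius_um, cost_model = cost_model,
                 flag_threshold = flag_threshold, unary_weight = unary_weight,
                 min_separation_um = min_separation_um,
                 prune_self_intersections = prune_self_intersections),
            class = "tracking_config")
}
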