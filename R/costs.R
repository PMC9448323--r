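#' Tracking cost models
#'
#' Four association cost models score a candidate posture against the
#' previous frame's posture. All are non-negative and exactly zero when the
#' candidate equals the previous state.
#'
#' * `cost_gnn`: the gated Global Nearest Neighbor (GNN) unary cost, the sum
#'   over nuclei of squared Euclidean displacement.
#' * `cost_embryo`: sum of squared edge-length differences over the embryo
#'   graph (a Mahalanobis form with identity weighting).
#' * `cost_posture`: edge-length differences weighted by the inverse of the
#'   estimated edge-length-difference covariance.
#' * `cost_movement`: stacked coordinate differences weighted by the inverse
#'   of the estimated 3n x 3n movement covariance; extends the GNN cost to
#'   penalize unnatural correlated motion.
#' * `cost_pm`: the additive Posture-Movement combination
#'   `cost_posture + cost_movement`.
#'
#' With identity covariances, `cost_posture` reduces exactly to
#' `cost_embryo` and `cost_movement` to `cost_gnn`.
#'
#' @param candidate,previous [posture_state()] objects over the same objects.
#' @param graph An [build_embryo_graph()] object.
#' @param model A `covariance_model` from [estimate_covariances()].
#' @return A single non-negative number.
#' @name cost_models
NULL

align_positions <- function(candidate, previous) {
  ids <- rownames(previous$positions)
  if (!all(ids %in% rownames(candidate$positions)))
    stop("candidate and previous states must contain the same objects")
  list(cand = candidate$positions[ids, , drop = FALSE],
       prev = previous$positions)
}

#' @rdname cost_models
#' @export
cost_gnn <- function(candidate, previous) {
  p <- align_positions(candidate, previous)
  sum((p$cand - p$prev)^2)
}

#' @rdname cost_models
#' @export
cost_embryo <- function(candidate, previous, graph) {
  d <- edge_length_vector(candidate, graph) - edge_length_vector(previous, graph)
  sum(d * d)
}

#' @rdname cost_models
#' @export
cost_posture <- function(candidate, previous, graph, model) {
  d <- edge_length_vector(candidate, graph) - edge_length_vector(previous, graph)
  if (length(d) != nrow(model$sigma_P_inv))
    stop("covariance model dimension does not match graph edge count")
  drop(t(d) %*% model$sigma_P_inv %*% d)
}

#' @rdname cost_models
#' @export
cost_movement <- function(candidate, previous, model) {
  ids <- model$nodes
  if (!all(ids %in% rownames(previous$positions)))
    stop("covariance model nodes do not match state")
  d <- as.vector(t(candidate$positions[ids, , drop = FALSE] -
                     previous$positions[ids, , drop = FALSE]))
  if (length(d) != nrow(model$sigma_M_inv))
    stop("covariance model dimension does not match state size")
  drop(t(d) %*% model$sigma_M_inv %*% d)
}

#' @rdname cost_models
#' @export
cost_pm <- function(candidate, previous, graph, model) {
  cost_posture(candidate, previous, graph, model) +
    cost_movement(candidate, previous, model)
}
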