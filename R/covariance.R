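#' Estimate posture and movement covariances from an annotated corpus
#'
#' The Posture and Movement cost models weight frame-to-frame differences by
#' inverse covariance matrices estimated from annotated tracks. For every
#' consecutive pair of frames in the corpus two difference vectors are
#' formed: the M-vector of edge-length differences over `graph`, and the
#' 3n-vector of stacked coordinate differences (per nucleus x, y, z, in
#' canonical node order). With T total frames (transitions pooled across
#' sequences), each covariance is the mean-centered outer-product sum scaled
#' by 1/(T-1), i.e. by the number of transitions, and then ridge-regularized
#' to be symmetric positive definite.
#'
#' @param corpus A `posture_sequence`, or a list of them.
#' @param graph An [build_embryo_graph()] object.
#' @param ridge Ridge coefficient; the matrix actually added is
#'   `ridge * mean(diag(Sigma)) * I` (scale-aware). Default `1e-6`.
#' @return An object of class `covariance_model`: list with `sigma_P`
#'   (M x M), `sigma_M` (3n x 3n), their inverses, the mean difference
#'   vectors `gbar_P` and `gbar_M`, `ridge`, `n_transitions`, and the node
#'   order `nodes`.
#' @export
estimate_covariances <- function(corpus, graph, ridge = 1e-6) {
  if (inherits(corpus, "posture_sequence")) corpus <- list(corpus)
  stopifnot(length(corpus) >= 1L)
  nodes <- graph$nodes
  dP <- list(); dM <- list()
  for (seqs in corpus) {
    if (length(seqs) < 2L) next
    E_prev <- edge_length_vector(seqs[[1L]], graph)
    Z_prev <- as.vector(t(seqs[[1L]]$positions[nodes, , drop = FALSE]))
    for (t in 2:length(seqs)) {
      E_cur <- edge_length_vector(seqs[[t]], graph)
      Z_cur <- as.vector(t(seqs[[t]]$positions[nodes, , drop = FALSE]))
      dP[[length(dP) + 1L]] <- E_cur - E_prev
      dM[[length(dM) + 1L]] <- Z_cur - Z_prev
      E_prev <- E_cur; Z_prev <- Z_cur
    }
  }
  n_tr <- length(dP)
  if (n_tr < 2L) stop("need at least 2 frame-to-frame transitions to estimate covariances")
  DP <- do.call(rbind, dP)
  DM <- do.call(rbind, dM)
  gbar_P <- colMeans(DP)
  gbar_M <- colMeans(DM)
  DP <- sweep(DP, 2L, gbar_P)
  DM <- sweep(DM, 2L, gbar_M)
  sigma_P <- crossprod(DP) / n_tr
  sigma_M <- crossprod(DM) / n_tr
  sigma_P <- regularize_spd(sigma_P, ridge)
  sigma_M <- regularize_spd(sigma_M, ridge)
  inv_P <- tryCatch(chol2inv(chol(sigma_P)),
                    error = function(e) stop("sigma_P singular after ridge"))
  inv_M <- tryCatch(chol2inv(chol(sigma_M)),
                    error = function(e) stop("sigma_M singular after ridge"))
  structure(
    list(sigma_P = sigma_P, sigma_M = sigma_M,
         sigma_P_inv = inv_P, sigma_M_inv = inv_M,
         gbar_P = gbar_P, gbar_M = gbar_M,
         ridge = ridge, n_transitions = n_tr, nodes = nodes,
         graph_fingerprint = graph_fingerprint(graph)),
    class = "covariance_model"
  )
}

regularize_spd <- function(S, ridge) {
  S <- (S + t(S)) / 2
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  S + diag(ridge * scale, nrow(S))
}

graph_fingerprint <- function(graph) {
  e <- graph$edges
  paste0("n", length(graph$nodes), ":M", graph$M, ":",
         format(sum(utf8ToInt(paste(e$from, e$to, collapse = ";")) *
                      seq_len(nchar(paste(e$from, e$to, collapse = ";"))) %% 1e9),
                scientific = FALSE))
}

#' Identity covariance model
#'
#' Convenience constructor for a `covariance_model` whose matrices are the
#' identity, under which the Posture model reduces exactly to the Embryo
#' model and the Movement model to the GNN cost.
#'
#' @param graph An [build_embryo_graph()] object.
#' @return A `covariance_model`.
#' @export
identity_covariance_model <- function(graph) {
  M <- graph$M; n3 <- 3L * length(graph$nodes)
  structure(
    list(sigma_P = diag(M), sigma_M = diag(n3),
         sigma_P_inv = diag(M), sigma_M_inv = diag(n3),
         gbar_P = rep(0, M), gbar_M = rep(0, n3),
         ridge = 0, n_transitions = 0L, nodes = graph$nodes,
         graph_fingerprint = graph_fingerprint(graph)),
    class = "covariance_model"
  )
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("<covariance_model> sigma_P %dx%d, sigma_M %dx%d, %d transitions, ridge %g\n",
              nrow(x$sigma_P), ncol(x$sigma_P), nrow(x$sigma_M), ncol(x$sigma_M),
              x$n_transitions, x$ridge))
  invisible(x)
}

#' Serialize / load a covariance model
#'
#' The model is written as JSON together with the fingerprint of the graph
#' it was estimated on, so a mismatched graph is detected at load time.
#'
#' @param model A `covariance_model`.
#' @param path File path.
#' @return `read_covariance_model` returns the restored `covariance_model`.
#' @export
write_covariance_model <- function(model, path) {
  obj <- list(
    sigma_P = model$sigma_P, sigma_M = model$sigma_M,
    gbar_P = model$gbar_P, gbar_M = model$gbar_M,
    ridge = model$ridge, n_transitions = model$n_transitions,
    nodes = model$nodes, graph_fingerprint = model$graph_fingerprint
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_covariance_model
#' @export
read_covariance_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sP <- as.matrix(obj$sigma_P); sM <- as.matrix(obj$sigma_M)
  structure(
    list(sigma_P = sP, sigma_M = sM,
         sigma_P_inv = chol2inv(chol(sP)), sigma_M_inv = chol2inv(chol(sM)),
         gbar_P = as.numeric(obj$gbar_P), gbar_M = as.numeric(obj$gbar_M),
         ridge = obj$ridge, n_transitions = obj$n_transitions,
         nodes = obj$nodes, graph_fingerprint = obj$graph_fingerprint),
    class = "covariance_model"
  )
}
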