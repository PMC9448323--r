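#' Canonical seam-cell identities
#'
#' The posture of a *C. elegans* embryo is defined by the joint position of
#' the 20 seam-cell nuclei: ten anterior-to-posterior ranks (H0, H1, H2,
#' V1-V6, T), each present on the left (`L`) and right (`R`) side of the
#' body. All posture containers in this package index nuclei by these names,
#' in the fixed order returned here: the ten left-side cells anterior to
#' posterior, then the ten right-side cells.
#'
#' @return Character vector of the 20 canonical ids, e.g. `"H0L"`, `"V3R"`.
#' @seealso [seam_cell_table()] for names, sides and ranks as a data frame.
#' @export
#' @examples
#' seam_cell_ids()
seam_cell_ids <- function() {
  ranks <- c("H0", "H1", "H2", "V1", "V2", "V3", "V4", "V5", "V6", "T")
  c(paste0(ranks, "L"), paste0(ranks, "R"))
}

#' Seam-cell name/side/rank table
#'
#' @return A data frame with one row per nucleus: `id`, `name` (H0..T),
#'   `side` ("L"/"R") and `rank` (0-based anterior-to-posterior index, 0-9).
#' @export
seam_cell_table <- function() {
  ranks <- c("H0", "H1", "H2", "V1", "V2", "V3", "V4", "V5", "V6", "T")
  data.frame(
    id = seam_cell_ids(),
    name = rep(ranks, 2L),
    side = rep(c("L", "R"), each = 10L),
    rank = rep(0:9, 2L),
    stringsAsFactors = FALSE
  )
}

#' Construct a posture state
#'
#' A posture state is the tracker's state at one frame: a named set of 3D
#' nucleus positions in micrometres. For the embryo this holds all 20
#' seam-cell nuclei, but the container (and the tracking machinery) accepts
#' any set of uniquely named objects, which keeps small constructed test
#' problems convenient.
#'
#' @param positions Numeric matrix with 3 columns (x, y, z in um) and row
#'   names giving object ids. For embryo postures use the ids of
#'   [seam_cell_ids()]; rows are reordered to canonical order when all 20
#'   are present.
#' @param frame 0-based frame index.
#' @param time_s Acquisition time in seconds; defaults to `frame / frame_rate`.
#' @param frame_rate Volumes per second (default 3, the posture imaging rate).
#' @param interpolated Character vector of ids whose positions were
#'   graphically interpolated rather than observed.
#' @return An object of class `posture_state`.
#' @export
posture_state <- function(positions, frame = 0L, time_s = NULL,
                          frame_rate = 3, interpolated = character()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must have 3 columns (x, y, z)")
  if (is.null(rownames(positions))) stop("positions must have row names (object ids)")
  if (anyDuplicated(rownames(positions))) stop("duplicate object ids")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (all(seam_cell_ids() %in% rownames(positions)) && nrow(positions) == 20L) {
    positions <- positions[seam_cell_ids(), , drop = FALSE]
  }
  colnames(positions) <- c("x", "y", "z")
  if (is.null(time_s)) time_s <- frame / frame_rate
  bad <- setdiff(interpolated, rownames(positions))
  if (length(bad)) stop("interpolated ids not in state: ", paste(bad, collapse = ", "))
  structure(
    list(frame = as.integer(frame), time_s = time_s,
         positions = positions, interpolated = interpolated),
    class = "posture_state"
  )
}

#' @export
print.posture_state <- function(x, ...) {
  cat(sprintf("<posture_state> frame %d (t = %.3f s), %d nuclei", x$frame,
              x$time_s, nrow(x$positions)))
  if (length(x$interpolated))
    cat(sprintf(", %d interpolated", length(x$interpolated)))
  cat("\n")
  invisible(x)
}

is_full_embryo_state <- function(state) {
  nrow(state$positions) == 20L && all(rownames(state$positions) == seam_cell_ids())
}

#' Bundle posture states into a sequence
#'
#' @param states List of [posture_state()] objects, in frame order.
#' @param frame_rate Volumes per second.
#' @return Object of class `posture_sequence` (a list with attributes).
#' @export
posture_sequence <- function(states, frame_rate = 3) {
  stopifnot(length(states) >= 1L, all(vapply(states, inherits, TRUE, "posture_state")))
  structure(states, class = "posture_sequence", frame_rate = frame_rate)
}

#' @export
print.posture_sequence <- function(x, ...) {
  cat(sprintf("<posture_sequence> %d frames at %g Hz, %d objects\n",
              length(x), attr(x, "frame_rate"), nrow(x[[1L]]$positions)))
  invisible(x)
}

#' Build the default embryo graph
#'
#' The anatomical lattice of seam-cell nuclei is encoded as a graph whose
#' edge-length changes quantify distortion of the embryo's shape between
#' frames. Edges run (i) along each side between nuclei of consecutive rank
#' (9 per side), (ii) laterally between the left/right members of each rank
#' (10), and (iii) diagonally across each consecutive rank quad (2 per quad,
#' 18), for M = 46 edges in total.
#'
#' @param ids Optional custom node ids (defaults to the 20 seam cells). When
#'   custom ids are supplied, `edges` must be given too.
#' @param edges Optional data frame with columns `from`, `to` and optionally
#'   `type`, to inject a non-default edge set over `ids`.
#' @return An object of class `embryo_graph`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `type`) and `M` (edge count).
#' @export
#' @examples
#' g <- build_embryo_graph()
#' g$M  # 46
build_embryo_graph <- function(ids = NULL, edges = NULL) {
  if (is.null(ids)) {
    ids <- seam_cell_ids()
    if (is.null(edges)) {
      tab <- seam_cell_table()
      side_edges <- do.call(rbind, lapply(c("L", "R"), function(s) {
        cells <- tab$id[tab$side == s][order(tab$rank[tab$side == s])]
        data.frame(from = cells[-10L], to = cells[-1L], type = "side",
                   stringsAsFactors = FALSE)
      }))
      left <- tab$id[tab$side == "L"][order(tab$rank[tab$side == "L"])]
      right <- tab$id[tab$side == "R"][order(tab$rank[tab$side == "R"])]
      lateral <- data.frame(from = left, to = right, type = "lateral",
                            stringsAsFactors = FALSE)
      diag1 <- data.frame(from = left[-10L], to = right[-1L], type = "diagonal",
                          stringsAsFactors = FALSE)
      diag2 <- data.frame(from = right[-10L], to = left[-1L], type = "diagonal",
                          stringsAsFactors = FALSE)
      edges <- rbind(side_edges, lateral, diag1, diag2)
    }
  }
  if (is.null(edges)) stop("edges must be supplied for custom node sets")
  edges$type <- if (is.null(edges$type)) "custom" else as.character(edges$type)
  stopifnot(all(edges$from %in% ids), all(edges$to %in% ids))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop("duplicate edges")
  g <- structure(list(nodes = ids, edges = edges, M = nrow(edges)),
                 class = "embryo_graph")
  if (!graph_is_connected(g)) stop("embryo graph must be connected")
  g
}

graph_is_connected <- function(graph) {
  n <- length(graph$nodes)
  idx <- stats::setNames(seq_len(n), graph$nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- idx[[graph$edges$from[k]]]; j <- idx[[graph$edges$to[k]]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

#' @export
print.embryo_graph <- function(x, ...) {
  cat(sprintf("<embryo_graph> %d nodes, %d edges (%s)\n", length(x$nodes), x$M,
              paste(sprintf("%s: %d", names(table(x$edges$type)),
                            as.integer(table(x$edges$type))), collapse = ", ")))
  invisible(x)
}

#' Adjacency (neighbor) lists of an embryo graph
#'
#' @param graph An [build_embryo_graph()] object.
#' @return Named list mapping each node id to the character vector of its
#'   graph neighbors.
#' @export
graph_neighbors <- function(graph) {
  nb <- stats::setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (k in seq_len(nrow(graph$edges))) {
    f <- graph$edges$from[k]; t <- graph$edges$to[k]
    nb[[f]] <- c(nb[[f]], t); nb[[t]] <- c(nb[[t]], f)
  }
  nb
}

#' Edge-length vector of a posture
#'
#' Component j is the Euclidean length of graph edge j evaluated on the
#' state's positions, in the graph's fixed edge order. Differences of this
#' vector between frames are the input of the Embryo and Posture cost models.
#'
#' @param state A [posture_state()] containing every graph node.
#' @param graph An [build_embryo_graph()] object.
#' @return Numeric vector of length `graph$M` (um).
#' @export
edge_length_vector <- function(state, graph) {
  pos <- state$positions
  missing <- setdiff(graph$nodes, rownames(pos))
  if (length(missing)) stop("state lacks nodes: ", paste(missing, collapse = ", "))
  d <- pos[graph$edges$from, , drop = FALSE] - pos[graph$edges$to, , drop = FALSE]
  unname(sqrt(rowSums(d * d)))
}
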