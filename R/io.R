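#' Write / read tracked postures as CSV
#'
#' Long format, one row per nucleus per frame: `frame` (0-based),
#' `time_s`, `cell_id`, `x_um`, `y_um`, `z_um`, `interpolated`, `flagged`.
#'
#' @param tracks An `mhht_tracks` object or a `posture_sequence`.
#' @param path Output file.
#' @return `read_tracks_csv` returns a list with `states` (a
#'   `posture_sequence`) and `flagged`.
#' @export
write_tracks_csv <- function(tracks, path) {
  states <- if (inherits(tracks, "mhht_tracks")) tracks$states else tracks
  flagged <- if (inherits(tracks, "mhht_tracks")) tracks$flagged
             else rep(FALSE, length(states))
  rows <- do.call(rbind, lapply(seq_along(states), function(t) {
    s <- states[[t]]
    data.frame(frame = s$frame, time_s = s$time_s,
               cell_id = rownames(s$positions),
               x_um = s$positions[, 1L], y_um = s$positions[, 2L],
               z_um = s$positions[, 3L],
               interpolated = rownames(s$positions) %in% s$interpolated,
               flagged = flagged[t], stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param frame_rate Frames per second used to rebuild states.
#' @export
read_tracks_csv <- function(path, frame_rate = 3) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  frames <- sort(unique(d$frame))
  states <- lapply(frames, function(f) {
    sub <- d[d$frame == f, ]
    pos <- as.matrix(sub[, c("x_um", "y_um", "z_um")])
    rownames(pos) <- sub$cell_id
    posture_state(pos, frame = f, time_s = sub$time_s[1L],
                  interpolated = sub$cell_id[sub$interpolated])
  })
  flagged <- vapply(frames, function(f) any(d$flagged[d$frame == f]),
                    logical(1L))
  list(states = posture_sequence(states, frame_rate = frame_rate),
       flagged = flagged)
}

#' Write / read detection sets as CSV
#'
#' Columns: `frame` (0-based), `time_s`, `cell_id` (source nucleus or
#' `CLUTTER`; empty when provenance is unknown), `x_um`, `y_um`, `z_um`.
#'
#' @param detections A `detection_sequence` (or plain list of matrices).
#' @param path Output file.
#' @param frame_rate Frames per second.
#' @return `read_detections_csv` returns a `detection_sequence`.
#' @export
write_detections_csv <- function(detections, path, frame_rate = 3) {
  det <- if (is.list(detections) && !is.null(detections$detections))
    detections$detections else detections
  prov <- if (!is.null(detections$provenance)) detections$provenance else NULL
  rows <- do.call(rbind, lapply(seq_along(det), function(t) {
    m <- det[[t]]
    if (!nrow(m)) return(NULL)
    data.frame(frame = t - 1L, time_s = (t - 1L) / frame_rate,
               cell_id = if (is.null(prov)) "" else prov[[t]],
               x_um = m[, 1L], y_um = m[, 2L], z_um = m[, 3L],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  frames <- seq.int(0L, max(d$frame))
  det <- lapply(frames, function(f) {
    sub <- d[d$frame == f, , drop = FALSE]
    unname(as.matrix(sub[, c("x_um", "y_um", "z_um")]))
  })
  prov <- lapply(frames, function(f) d$cell_id[d$frame == f])
  structure(list(detections = det, provenance = prov),
            class = "detection_sequence")
}

#' Write a multi-page TIFF movie / read it back
#'
#' Images are stored as 16-bit grayscale; intensities are counts in
#' [0, 65535].
#'
#' @param images List of numeric matrices (counts).
#' @param path TIFF path.
#' @return `read_movie_tiff` returns a list of matrices in counts.
#' @export
write_movie_tiff <- function(images, path) {
  tiff::writeTIFF(lapply(images, function(m) m / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) round(m * 65535))
}

#' Serialize an eigen-embryo basis to JSON
#'
#' @param basis An `eigen_basis`.
#' @param path File path.
#' @return `read_eigen_basis` returns the restored `eigen_basis`.
#' @export
write_eigen_basis <- function(basis, path) {
  jsonlite::write_json(unclass(basis), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_eigen_basis
#' @export
read_eigen_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$components <- as.matrix(obj$components)
  obj$mean_profile <- as.numeric(obj$mean_profile)
  structure(obj, class = "eigen_basis")
}
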