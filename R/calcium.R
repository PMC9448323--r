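#' Construct a calcium trace
#'
#' Ratiometric (GCaMP/mCherry) activity of a tracked cell body plus its 3D
#' position, sampled at 1 Hz.
#'
#' @param time_s Sample times (seconds).
#' @param gcamp,mcherry Intensity series.
#' @param position_um n x 3 matrix of cell positions (um), or `NULL`.
#' @param embryo_id Identifier.
#' @param valid Logical mask of frames with a usable localization.
#' @return Object of class `calcium_trace`; `dr_over_r0` is filled by
#'   [compute_dr_over_r0()].
#' @export
calcium_trace <- function(time_s, gcamp, mcherry, position_um = NULL,
                          embryo_id = "embryo", valid = NULL) {
  n <- length(time_s)
  stopifnot(length(gcamp) == n, length(mcherry) == n)
  if (!is.null(position_um)) {
    position_um <- as.matrix(position_um)
    stopifnot(nrow(position_um) == n, ncol(position_um) == 3L)
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  structure(list(time_s = time_s, gcamp = gcamp, mcherry = mcherry,
                 position_um = position_um, dr_over_r0 = NULL,
                 embryo_id = embryo_id, valid = valid),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> '%s': %d s%s\n", x$embryo_id, length(x$time_s),
              if (is.null(x$dr_over_r0)) "" else ", dR/R0 computed"))
  invisible(x)
}

#' Localize a cell body and extract its dual-channel trace
#'
#' Per frame: 100 counts of camera background are subtracted (clamped at
#' zero), every z-plane of both channels is smoothed with a Gaussian kernel
#' (sigma 5 px, symmetric padding), the cell position is the brightest
#' voxel of the filtered mCherry volume, and the GCaMP intensity is read
#' from the filtered GCaMP channel at that voxel. Frames whose filtered
#' mCherry volume is featureless (constant) are flagged invalid.
#'
#' @param volumes List of frames; each frame is `list(gcamp = , mcherry = )`
#'   of 3D arrays (y, x, z).
#' @param voxel_um Physical voxel size `c(y, x, z)` in um.
#' @param background Camera background counts to subtract (default 100).
#' @param sigma Gaussian kernel SD in pixels (default 5).
#' @param frame_rate Volumes per second (default 1).
#' @param embryo_id Identifier.
#' @return A [calcium_trace()] with positions in um and a `valid` mask.
#' @export
extract_cell_trace <- function(volumes, voxel_um = c(1, 1, 1),
                               background = 100, sigma = 5, frame_rate = 1,
                               embryo_id = "embryo") {
  n <- length(volumes)
  gc <- mc <- numeric(n)
  pos <- matrix(NA_real_, n, 3L)
  valid <- logical(n)
  for (t in seq_len(n)) {
    vol_m <- pmax(volumes[[t]]$mcherry - background, 0)
    vol_g <- pmax(volumes[[t]]$gcamp - background, 0)
    nz <- dim(vol_m)[3L]
    fm <- array(0, dim(vol_m)); fg <- array(0, dim(vol_g))
    for (z in seq_len(nz)) {
      fm[, , z] <- gaussian_blur(vol_m[, , z], sigma)
      fg[, , z] <- gaussian_blur(vol_g[, , z], sigma)
    }
    if (max(fm) - min(fm) < .Machine$double.eps * max(1, max(fm))) {
      valid[t] <- FALSE
      next
    }
    idx <- arrayInd(which.max(fm), dim(fm))
    pos[t, ] <- (idx - 1L) * voxel_um
    mc[t] <- fm[idx]
    gc[t] <- fg[idx]
    valid[t] <- TRUE
  }
  tr <- calcium_trace(time_s = (seq_len(n) - 1L) / frame_rate, gcamp = gc,
                      mcherry = mc, position_um = pos, embryo_id = embryo_id,
                      valid = valid)
  tr
}

#' Baseline-normalized GCaMP/mCherry ratio
#'
#' `R = GCaMP / mCherry` per frame; the baseline `R0` is the 10th
#' percentile of `R` over the trace, and `dR/R0 = (R - R0) / R0`.
#'
#' @param trace A [calcium_trace()].
#' @return The trace with `dr_over_r0` (and `r0`) filled in.
#' @export
compute_dr_over_r0 <- function(trace) {
  if (any(trace$mcherry <= 0))
    stop("mCherry must be positive everywhere after preprocessing")
  R <- trace$gcamp / trace$mcherry
  r0 <- stats::quantile(R, 0.10, names = FALSE)
  if (r0 == 0) stop("zero baseline ratio")
  trace$dr_over_r0 <- (R - r0) / r0
  trace$r0 <- r0
  trace
}

#' Detect calcium transients with hysteresis thresholds
#'
#' On the trailing moving-mean (span 4) of the dR/R0 trace, an event opens
#' at the first sample at or above `onset_thr` and closes at the first
#' subsequent sample below `offset_thr` (hysteresis: excursions between the
#' thresholds do not retrigger). The event amplitude is the smoothed peak;
#' its duration is the full width at half that peak, with linearly
#' interpolated crossings; the half-peak onset time is the alignment zero
#' used by [align_to_transient_onset()]. The default thresholds (2.0 / 1.5)
#' are for RIS cell bodies; ALA neurite traces use 0.07 / 0.05.
#'
#' @param trace A [calcium_trace()] with `dr_over_r0`, or a numeric series.
#' @param onset_thr,offset_thr Hysteresis thresholds (onset > offset).
#' @param smooth_span Trailing moving-mean span (samples).
#' @param frame_rate Samples per second.
#' @return Data frame of class `transient_events`: `onset_frame`,
#'   `offset_frame` (1-based; offset is the first sub-threshold frame, or
#'   one past the trace end), `peak_amplitude`, `half_peak_onset_s`,
#'   `duration_s`.
#' @export
detect_transients <- function(trace, onset_thr = 2.0, offset_thr = 1.5,
                              smooth_span = 4L, frame_rate = 1) {
  if (onset_thr <= offset_thr)
    stop("onset threshold must exceed offset threshold")
  x <- if (inherits(trace, "calcium_trace")) {
    if (is.null(trace$dr_over_r0)) stop("run compute_dr_over_r0() first")
    trace$dr_over_r0
  } else as.numeric(trace)
  sm <- trailing_mean(x, smooth_span)
  n <- length(sm)
  events <- data.frame(onset_frame = integer(), offset_frame = integer(),
                       peak_amplitude = numeric(),
                       half_peak_onset_s = numeric(), duration_s = numeric())
  t <- 1L
  while (t <= n) {
    if (sm[t] >= onset_thr) {
      onset <- t
      t2 <- t
      while (t2 <= n && sm[t2] >= offset_thr) t2 <- t2 + 1L
      offset <- t2  # first sub-threshold sample (n + 1 if the trace ends high)
      span <- onset:min(offset - 1L, n)
      pk_rel <- which.max(sm[span])
      pk <- span[pk_rel]
      amp <- sm[pk]
      half <- amp / 2
      cross_left <- half_cross(sm, pk, half, -1L)
      cross_right <- half_cross(sm, pk, half, +1L)
      events <- rbind(events, data.frame(
        onset_frame = onset, offset_frame = offset, peak_amplitude = amp,
        half_peak_onset_s = (cross_left - 1) / frame_rate,
        duration_s = (cross_right - cross_left) / frame_rate))
      t <- offset
    } else t <- t + 1L
  }
  class(events) <- c("transient_events", class(events))
  events
}

# Interpolated index where the series crosses `level` walking from `pk`
# in direction `dir`; trace ends clamp to the boundary index.
half_cross <- function(sm, pk, level, dir) {
  n <- length(sm)
  i <- pk
  while (i + dir >= 1L && i + dir <= n && sm[i + dir] >= level) i <- i + dir
  j <- i + dir
  if (j < 1L || j > n) return(i)
  # linear interpolation between samples i (>= level) and j (< level)
  i + dir * (sm[i] - level) / (sm[i] - sm[j])
}

#' Detect quiescent bouts from cell displacement
#'
#' Per-second displacements of the tracked cell are computed; maximal runs
#' with displacement at or below `speed_thr` lasting at least `min_dur_s`
#' become quiescent bouts.
#'
#' @param position_um n x 3 position matrix (or a [calcium_trace()]).
#' @param speed_thr Displacement threshold (um per second, default 0.5).
#' @param min_dur_s Minimum bout duration (default 3 s).
#' @param frame_rate Samples per second (default 1).
#' @return Data frame: `start_s`, `end_s`, `duration_s`.
#' @export
detect_quiescence <- function(position_um, speed_thr = 0.5, min_dur_s = 3,
                              frame_rate = 1) {
  pos <- if (inherits(position_um, "calcium_trace")) position_um$position_um
         else as.matrix(position_um)
  d <- sqrt(rowSums((pos[-1L, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE])^2))
  quiet <- d <= speed_thr
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths / frame_rate >= min_dur_s)
  data.frame(start_s = (starts[keep] - 1L) / frame_rate,
             end_s = ends[keep] / frame_rate,
             duration_s = r$lengths[keep] / frame_rate)
}

#' Event-aligned traces around transient onsets
#'
#' For every detected transient, a window around its half-peak onset time
#' (the alignment zero) is extracted from the embryo's median-normalized
#' speed, GCaMP and mCherry series. Events whose window would run off the
#' trace are dropped and counted.
#'
#' @param traces List of [calcium_trace()] objects (with positions).
#' @param events List of [detect_transients()] outputs, matching `traces`.
#' @param window Window around the alignment zero, `c(-30, 60)` seconds.
#' @param frame_rate Samples per second.
#' @return List: `time_s`, per-event matrices `speed`, `gcamp`, `mcherry`,
#'   `embryo` (id per event row), the across-event `mean` traces, and
#'   `n_dropped`.
#' @export
align_to_transient_onset <- function(traces, events, window = c(-30, 60),
                                     frame_rate = 1) {
  stopifnot(length(traces) == length(events))
  rel <- seq.int(window[1L] * frame_rate, window[2L] * frame_rate)
  time_s <- rel / frame_rate
  rows_speed <- list(); rows_g <- list(); rows_m <- list(); emb <- character()
  dropped <- 0L
  for (e in seq_along(traces)) {
    tr <- traces[[e]]
    n <- length(tr$time_s)
    spd <- c(NA_real_, sqrt(rowSums((tr$position_um[-1L, , drop = FALSE] -
                                       tr$position_um[-n, , drop = FALSE])^2))) *
      frame_rate
    mednorm <- function(v) {
      m <- stats::median(v, na.rm = TRUE)
      if (isTRUE(m == 0)) v else v / m
    }
    spd <- mednorm(spd); g <- mednorm(tr$gcamp); mch <- mednorm(tr$mcherry)
    for (k in seq_len(nrow(events[[e]]))) {
      center <- round(events[[e]]$half_peak_onset_s[k] * frame_rate) + 1L
      idx <- center + rel
      if (min(idx) < 1L || max(idx) > n) { dropped <- dropped + 1L; next }
      rows_speed[[length(rows_speed) + 1L]] <- spd[idx]
      rows_g[[length(rows_g) + 1L]] <- g[idx]
      rows_m[[length(rows_m) + 1L]] <- mch[idx]
      emb <- c(emb, tr$embryo_id)
    }
  }
  tomat <- function(rows) if (length(rows)) do.call(rbind, rows)
                          else matrix(numeric(), 0L, length(rel))
  speed <- tomat(rows_speed); g <- tomat(rows_g); m <- tomat(rows_m)
  list(time_s = time_s, speed = speed, gcamp = g, mcherry = m, embryo = emb,
       mean = list(speed = colMeans(speed), gcamp = colMeans(g),
                   mcherry = colMeans(m)),
       n_dropped = dropped)
}

#' Hierarchical bootstrap of event-aligned means
#'
#' Each replicate resamples embryos with replacement, then events within
#' each sampled embryo with replacement; the replicate statistic is the
#' mean trace across all resampled events. The pointwise mean and SD of the
#' replicate statistics estimate the sampling distribution of the
#' event-aligned mean under the nested (events within embryos) design.
#'
#' @param event_matrix Events x time matrix (e.g. `$speed` from
#'   [align_to_transient_onset()]).
#' @param embryo_ids Embryo id per event row.
#' @param n_boot Number of replicates.
#' @param seed RNG seed.
#' @return List: `mean` and `sd` per time point, and `n_boot`.
#' @export
hierarchical_bootstrap <- function(event_matrix, embryo_ids, n_boot = 1000L,
                                   seed = 1L) {
  event_matrix <- as.matrix(event_matrix)
  stopifnot(nrow(event_matrix) == length(embryo_ids))
  groups <- split(seq_len(nrow(event_matrix)), embryo_ids)
  if (length(groups) == 1L)
    warning("single embryo: the upper bootstrap level is degenerate")
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      gs <- sample(length(groups), replace = TRUE)
      idx <- unlist(lapply(gs, function(g) {
        rows <- groups[[g]]
        rows[sample.int(length(rows), replace = TRUE)]
      }), use.names = FALSE)
      colMeans(event_matrix[idx, , drop = FALSE])
    }, numeric(ncol(event_matrix)))
  })
  reps <- if (is.matrix(reps)) t(reps) else matrix(reps, ncol = 1L)
  list(mean = colMeans(reps), sd = apply(reps, 2L, stats::sd),
       n_boot = n_boot)
}

#' Categorize a stimulus trial by RIS state
#'
#' A trial is `RIS_on` when the stimulus onset falls inside any detected
#' transient (event onset inclusive, offset exclusive), else `RIS_off`.
#' Mean dR/R0 and speed are reported for the pre-stimulus, stimulus and
#' post-stimulus windows.
#'
#' @param events [detect_transients()] output for the trial's trace.
#' @param stim_onset_s Stimulus onset time (seconds from trace start).
#' @param trace The [calcium_trace()] (with `dr_over_r0` and positions).
#' @param pre_s,stim_s,post_s Window lengths (default 10 s each).
#' @param frame_rate Samples per second.
#' @return List: `label` (`"RIS_on"`/`"RIS_off"`) and `windows` (data frame
#'   with mean activity and speed per window).
#' @export
categorize_stimulus_trials <- function(events, stim_onset_s, trace,
                                       pre_s = 10, stim_s = 10, post_s = 10,
                                       frame_rate = 1) {
  n <- length(trace$time_s)
  stim_idx <- round(stim_onset_s * frame_rate) + 1L
  if (stim_idx < 1L || stim_idx > n) stop("stimulus lies outside the trace")
  on <- FALSE
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      if (stim_idx >= events$onset_frame[k] && stim_idx < events$offset_frame[k]) {
        on <- TRUE
        break
      }
    }
  }
  spd <- c(NA_real_, sqrt(rowSums((trace$position_um[-1L, , drop = FALSE] -
                                     trace$position_um[-n, , drop = FALSE])^2))) *
    frame_rate
  win_mean <- function(v, a, b) {
    ia <- max(1L, round(a * frame_rate) + 1L)
    ib <- min(n, round(b * frame_rate))
    mean(v[ia:ib], na.rm = TRUE)
  }
  wins <- data.frame(
    window = c("pre", "stim", "post"),
    start_s = c(stim_onset_s - pre_s, stim_onset_s, stim_onset_s + stim_s),
    end_s = c(stim_onset_s, stim_onset_s + stim_s,
              stim_onset_s + stim_s + post_s))
  wins$mean_dr_over_r0 <- mapply(function(a, b) win_mean(trace$dr_over_r0, a, b),
                                 wins$start_s, wins$end_s)
  wins$mean_speed <- mapply(function(a, b) win_mean(spd, a, b),
                            wins$start_s, wins$end_s)
  list(label = if (on) "RIS_on" else "RIS_off", windows = wins)
}
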