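#' Mean squared displacement of a trajectory
#'
#' `MSD(tau)` is the mean over all admissible overlapping pairs of the
#' squared displacement at lag `tau`.
#'
#' @param track Numeric matrix (frames x 3) of positions (um).
#' @param frame_rate Frames per second.
#' @param max_lag Largest lag in frames (default all).
#' @return Data frame: `lag` (frames), `tau_s`, `msd` (um^2), `n_pairs`.
#' @export
compute_msd <- function(track, frame_rate = 3, max_lag = NULL) {
  track <- as.matrix(track)
  n <- nrow(track)
  if (n < 2L) stop("track must have at least 2 frames")
  if (is.null(max_lag)) max_lag <- n - 1L
  max_lag <- min(max_lag, n - 1L)
  lag <- seq_len(max_lag)
  msd <- vapply(lag, function(L) {
    d <- track[(L + 1L):n, , drop = FALSE] - track[seq_len(n - L), , drop = FALSE]
    mean(rowSums(d * d))
  }, numeric(1L))
  data.frame(lag = lag, tau_s = lag / frame_rate, msd = msd, n_pairs = n - lag)
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary least squares (with intercept) of `MSD` against lag time over
#' the first `fit_lags` lags (default 30 frames = 10 s at 3 Hz);
#' `D = slope / (2 * dims)` for free diffusion `MSD = 2 * dims * D * tau`.
#'
#' @param msd Output of [compute_msd()].
#' @param fit_lags Number of leading lags used in the fit.
#' @param dims Spatial dimensionality (3).
#' @return Diffusion coefficient `D` (um^2/s).
#' @export
estimate_diffusion_coefficient <- function(msd, fit_lags = 30L, dims = 3L) {
  if (nrow(msd) < fit_lags) {
    warning("fewer than ", fit_lags, " lags available; fitting over all ",
            nrow(msd))
    fit_lags <- nrow(msd)
  }
  sub <- msd[seq_len(fit_lags), , drop = FALSE]
  fit <- stats::lm(msd ~ tau_s, data = sub)
  unname(stats::coef(fit)[2L] / (2 * dims))
}

#' Embryo speed and direction of motion
#'
#' For the seven lateral-pair midpoints H1..V5, displacement is measured
#' over `window` frames (1 s at 3 Hz). The embryo speed is the weighted
#' mean of per-midpoint speeds, with weights proportional to the
#' straight-line lengths of the two midline segments adjacent to each
#' midpoint. The angle `theta` of each midpoint's displacement is measured
#' against the local anterior tangent (the normalized vector from midpoint
#' rank+1 to rank-1), and `theta_bar` is their mean. States: `pause` when
#' speed is below `pause_threshold` (pauses take priority), else `forward`
#' (`theta_bar < 45` degrees), `backward` (`theta_bar > 135`), else
#' `other`.
#'
#' @param states A `posture_sequence` of complete embryo postures.
#' @param frame_rate Frames per second (default 3).
#' @param window Displacement window in frames (default 3 = 1 s).
#' @param pause_threshold Speed below which a frame is a pause (um/s).
#' @return Data frame of class `motion_samples`: `frame` (index into
#'   `states`), `time_s`, `speed_um_per_s`, `theta_deg`, `state`. Frames
#'   without a full displacement window are dropped.
#' @export
compute_speed_direction <- function(states, frame_rate = 3, window = 3L,
                                    pause_threshold = 0.5) {
  TT <- length(states)
  if (TT < window + 1L) stop("need at least window + 1 frames at 3 Hz")
  tab <- seam_cell_table()
  left <- tab$id[tab$side == "L"][order(tab$rank[tab$side == "L"])]
  right <- tab$id[tab$side == "R"][order(tab$rank[tab$side == "R"])]
  mids <- lapply(states, function(s) {
    if (!is_full_embryo_state(s)) stop("incomplete posture state")
    (s$positions[left, , drop = FALSE] + s$positions[right, , drop = FALSE]) / 2
  })
  interior <- 2:8  # midpoint ranks H1..V5 (rows 2..8 of the 10 midpoints)
  out <- data.frame(frame = integer(), time_s = numeric(),
                    speed_um_per_s = numeric(), theta_deg = numeric(),
                    state = character(), stringsAsFactors = FALSE)
  for (t in seq.int(window + 1L, TT)) {
    m_now <- mids[[t]]
    m_prev <- mids[[t - window]]
    seg <- m_now[-1L, , drop = FALSE] - m_now[-10L, , drop = FALSE]
    seglen <- sqrt(rowSums(seg * seg))  # segment r connects rank r to r+1
    w <- (seglen[interior - 1L] + seglen[interior]) / 2
    w <- w / sum(w)
    disp <- (m_now - m_prev)[interior, , drop = FALSE]
    dt <- window / frame_rate
    spd <- sqrt(rowSums(disp * disp)) / dt
    speed <- sum(w * spd)
    theta <- vapply(seq_along(interior), function(k) {
      r <- interior[k]
      ant <- m_now[r - 1L, ] - m_now[r + 1L, ]  # anterior-pointing tangent
      na <- sqrt(sum(ant * ant))
      nd <- sqrt(sum(disp[k, ]^2))
      if (na == 0 || nd == 0) return(NA_real_)
      cth <- sum(ant * disp[k, ]) / (na * nd)
      acos(max(-1, min(1, cth))) * 180 / pi
    }, numeric(1L))
    theta_bar <- mean(theta, na.rm = TRUE)
    st <- if (speed < pause_threshold) "pause"
          else if (is.nan(theta_bar)) "other"
          else if (theta_bar < 45) "forward"
          else if (theta_bar > 135) "backward"
          else "other"
    out <- rbind(out, data.frame(frame = t, time_s = states[[t]]$time_s,
                                 speed_um_per_s = speed,
                                 theta_deg = theta_bar, state = st,
                                 stringsAsFactors = FALSE))
  }
  class(out) <- c("motion_samples", class(out))
  out
}

#' Segment motion samples into behavioral bouts
#'
#' Maximal runs of identical state become bouts.
#'
#' @param samples Output of [compute_speed_direction()] (or any data frame
#'   with `frame` and `state`).
#' @param frame_rate Frames per second.
#' @return Data frame: `state`, `start_frame`, `end_frame`, `duration_s`.
#' @export
segment_bouts <- function(samples, frame_rate = 3) {
  r <- rle(samples$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(state = r$values,
             start_frame = samples$frame[starts],
             end_frame = samples$frame[ends],
             duration_s = r$lengths / frame_rate,
             stringsAsFactors = FALSE)
}

#' Binned summary statistics
#'
#' Values are grouped into non-overlapping time bins from the recording
#' start; per bin, the mean, standard error and coefficient of variation
#' (sample SD / mean) are reported. A zero-mean bin has undefined CV and is
#' flagged.
#'
#' @param values Numeric series.
#' @param time_s Sample times (seconds), same length as `values`.
#' @param bin_minutes Bin width (default 20 minutes).
#' @return Data frame: `bin`, `start_min`, `n`, `mean`, `sem`, `cv`,
#'   `cv_defined`.
#' @export
binned_stats <- function(values, time_s, bin_minutes = 20) {
  stopifnot(length(values) == length(time_s))
  t0 <- time_s - min(time_s)
  bin <- floor(t0 / (bin_minutes * 60)) + 1L
  idx <- split(seq_along(values), bin)
  out <- do.call(rbind, lapply(names(idx), function(b) {
    v <- values[idx[[b]]]
    m <- mean(v)
    s <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(bin = as.integer(b),
               start_min = (as.integer(b) - 1L) * bin_minutes,
               n = length(v), mean = m,
               sem = s / sqrt(length(v)),
               cv = if (m == 0) NA_real_ else s / m,
               cv_defined = m != 0)
  }))
  rownames(out) <- NULL
  out
}
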