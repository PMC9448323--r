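#' Centered moving mean, truncated at the edges
#'
#' @param x Numeric series.
#' @param width Window width in samples (default 30 = 30 s at 1 Hz).
#' @return Smoothed series of the same length.
#' @export
smooth_tally <- function(x, width = 30L) {
  zoo::rollapply(zoo::zoo(x), width, mean, partial = TRUE, align = "center")
}

#' Construct a twitch profile
#'
#' Per-second pixel-change tallies from the brightfield motility assay,
#' with the detected onset/hatch indices and an exclusion mask for frames
#' contaminated by background motion (e.g. hatchlings swimming through).
#'
#' @param tally Integer series of pixels changing per second (0..441 for
#'   the 21 x 21 analysis box).
#' @param embryo_id Identifier.
#' @param excluded Logical mask, `TRUE` for excluded frames.
#' @param onset_frame,hatch_frame 1-based indices or `NA`.
#' @return Object of class `twitch_profile`.
#' @export
twitch_profile <- function(tally, embryo_id = "embryo", excluded = NULL,
                           onset_frame = NA_integer_, hatch_frame = NA_integer_) {
  tally <- as.numeric(tally)
  if (any(tally < 0 | tally > 441, na.rm = TRUE))
    stop("tally values must lie in [0, 441]")
  if (is.null(excluded)) excluded <- rep(FALSE, length(tally))
  stopifnot(length(excluded) == length(tally))
  if (!is.na(onset_frame) && !is.na(hatch_frame) && onset_frame >= hatch_frame)
    stop("onset must precede hatch")
  structure(list(embryo_id = embryo_id, tally = tally, excluded = excluded,
                 onset_frame = onset_frame, hatch_frame = hatch_frame),
            class = "twitch_profile")
}

#' @export
print.twitch_profile <- function(x, ...) {
  cat(sprintf("<twitch_profile> '%s': %d s, onset %s, hatch %s, %d excluded\n",
              x$embryo_id, length(x$tally),
              ifelse(is.na(x$onset_frame), "?", x$onset_frame),
              ifelse(is.na(x$hatch_frame), "?", x$hatch_frame),
              sum(x$excluded)))
  invisible(x)
}

#' Pixel-change tally trace from a brightfield image series
#'
#' For a square box centered on the embryo, `tally[t]` counts the box
#' pixels whose intensity changed by more than `change_threshold` counts
#' between frames `t - 1` and `t`; the first frame tallies 0.
#'
#' @param images List of image matrices (same dimensions, 1 Hz).
#' @param center Pixel coordinates `c(row, col)` of the embryo center.
#' @param change_threshold Intensity change threshold (default 25 counts).
#' @param box_size Box side in pixels (default 21, giving 441 pixels).
#' @return Integer tally series.
#' @export
compute_tally_trace <- function(images, center, change_threshold = 25,
                                box_size = 21L) {
  half <- (box_size - 1L) %/% 2L
  rows <- (center[1L] - half):(center[1L] + half)
  cols <- (center[2L] - half):(center[2L] + half)
  dm <- dim(images[[1L]])
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > dm[1L] || max(cols) > dm[2L])
    stop("analysis box exceeds image bounds")
  tally <- integer(length(images))
  prev <- images[[1L]][rows, cols]
  for (t in seq_along(images)[-1L]) {
    cur <- images[[t]][rows, cols]
    tally[t] <- sum(abs(cur - prev) > change_threshold)
    prev <- cur
  }
  tally
}

#' Detect twitch onset
#'
#' Onset is the first frame at which the tally, smoothed with a centered
#' 30-frame moving mean, exceeds `threshold` (120 of a potential 441
#' pixels).
#'
#' @param tally Tally series (1 Hz).
#' @param threshold Smoothed-tally onset criterion.
#' @param smooth_frames Smoothing window.
#' @return 1-based frame index, or `NA` if never crossed.
#' @export
detect_onset <- function(tally, threshold = 120, smooth_frames = 30L) {
  sm <- smooth_tally(tally, smooth_frames)
  idx <- which(sm > threshold)
  if (!length(idx)) NA_integer_ else idx[1L]
}

#' Detect hatching
#'
#' Hatch is the first frame at which the smoothed mean intensity at the
#' embryo position reaches `ratio_threshold` (0.92) of the smoothed
#' background-perimeter mean intensity, i.e. the embryo has vacated its
#' position.
#'
#' @param embryo_intensity Mean embryo-box intensity per frame.
#' @param background_intensity Mean background-perimeter intensity per frame.
#' @param ratio_threshold Signal-to-background criterion (default 0.92).
#' @param smooth_frames Smoothing window (default 30).
#' @return 1-based frame index, or `NA`. A series that starts at or above
#'   the criterion returns the first valid index with a warning.
#' @export
detect_hatch <- function(embryo_intensity, background_intensity,
                         ratio_threshold = 0.92, smooth_frames = 30L) {
  if (any(background_intensity <= 0)) stop("background intensity must be positive")
  r <- smooth_tally(embryo_intensity, smooth_frames) /
    smooth_tally(background_intensity, smooth_frames)
  idx <- which(r >= ratio_threshold)
  if (!length(idx)) return(NA_integer_)
  if (idx[1L] == 1L)
    warning("signal-to-background ratio starts at or above the hatch criterion")
  idx[1L]
}

#' Exclusion mask for contaminated frames
#'
#' A frame is excluded when the 30-frame-smoothed count of
#' background-perimeter pixels changing by more than their threshold
#' exceeds `max_pixels` (40 of a potential 240), indicating motion in the
#' background (e.g. a hatchling crossing the field).
#'
#' @param background_changes Per-frame counts of background-perimeter
#'   pixels changing by more than the background threshold (35 counts).
#' @param max_pixels Exclusion criterion (strict `>`).
#' @param smooth_frames Smoothing window.
#' @return Logical mask.
#' @export
build_exclusion_mask <- function(background_changes, max_pixels = 40,
                                 smooth_frames = 30L) {
  as.vector(smooth_tally(background_changes, smooth_frames) > max_pixels)
}

#' Fill gaps by reversed duplication of the preceding interval
#'
#' Each run of `NA` of length L is replaced with the immediately preceding
#' L values in reversed order. Gaps are filled left to right, so a later
#' gap may draw on earlier filled values.
#'
#' @param x Numeric series with `NA` gaps.
#' @return Gap-free series.
#' @export
fill_missing <- function(x) {
  isna <- is.na(x)
  if (!any(isna)) return(x)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    L <- r$lengths[k]
    s <- starts[k]
    if (s - L < 1L)
      stop("gap at position ", s, " lacks ", L, " preceding values")
    fill <- x[(s - L):(s - 1L)]
    if (anyNA(fill)) stop("preceding interval itself contains missing values")
    x[s:(s + L - 1L)] <- rev(fill)
  }
  x
}

#' Slow-wave-twitch power ratio of one window
#'
#' The window is discrete-Fourier transformed and the SWT power ratio is
#' the summed squared magnitude over frequency bins with
#' 20 mHz <= f <= 40 mHz divided by the sum over 0 <= f <= 500 mHz (DC
#' included). At the 1/900 Hz bin spacing of a 15-minute window the band
#' edges fall exactly on bins 18 and 36.
#'
#' @param window Numeric series of exactly `window_s` samples at 1 Hz,
#'   gap-free.
#' @param band Passband in Hz (default `c(0.02, 0.04)`).
#' @param window_s Required window length in seconds (default 900).
#' @param detrend Subtract the window mean first (off by default: the
#'   printed definition includes the DC bin).
#' @return Ratio in `[0, 1]`.
#' @export
swt_power_ratio <- function(window, band = c(0.02, 0.04), window_s = 900L,
                            detrend = FALSE) {
  n <- length(window)
  if (n != window_s) stop("window must contain exactly ", window_s, " samples")
  if (anyNA(window)) stop("window contains missing values; fill gaps first")
  x <- if (detrend) window - mean(window) else window
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1L) / n
  eps <- 1e-12
  num <- sum(p[f >= band[1L] - eps & f <= band[2L] + eps])
  den <- sum(p[f <= 0.5 + eps])
  if (den == 0) return(0)
  num / den
}

swt_window_starts <- function(onset, hatch, start_offset_s, window_s, step_s) {
  first <- onset + start_offset_s
  if (first + window_s - 1L > hatch) return(integer())
  seq.int(first, hatch - window_s + 1L, by = step_s)
}

#' Scan a twitch profile for peak SWT power
#'
#' 15-minute windows are slid (200 s steps) from 1 hour after twitch onset
#' until hatching; excluded frames are gap-filled by reversed duplication
#' ([fill_missing()]) before windowing. The timing and magnitude of the
#' largest SWT power ratio are recorded; window timing is reported at the
#' window center, converted to minutes post-fertilization via the
#' convention that twitch onset is 430 mpf.
#'
#' @param profile A [twitch_profile()] with known onset and hatch.
#' @param window_s,step_s,start_offset_s Scan geometry in seconds.
#' @param band Passband in Hz.
#' @param onset_mpf Embryo age at twitch onset (430 mpf).
#' @param detrend Passed to [swt_power_ratio()].
#' @return Object of class `swt_result`: data frame of windows
#'   (`start_s`, `center_mpf`, `power_ratio`) plus `peak_ratio` and
#'   `peak_time_mpf`.
#' @export
scan_peak_swt <- function(profile, window_s = 900L, step_s = 200L,
                          start_offset_s = 3600L, band = c(0.02, 0.04),
                          onset_mpf = 430, detrend = FALSE) {
  if (is.na(profile$onset_frame) || is.na(profile$hatch_frame))
    stop("onset and hatch must be known to scan for SWT")
  x <- profile$tally
  x[profile$excluded] <- NA_real_
  x <- fill_missing(x)
  starts <- swt_window_starts(profile$onset_frame, profile$hatch_frame,
                              start_offset_s, window_s, step_s)
  if (!length(starts)) stop("no full window between onset + offset and hatch")
  ratios <- vapply(starts, function(s)
    swt_power_ratio(x[s:(s + window_s - 1L)], band = band,
                    window_s = window_s, detrend = detrend), numeric(1L))
  center_mpf <- onset_mpf + (starts - profile$onset_frame + window_s / 2) / 60
  k <- which.max(ratios)
  structure(list(
    windows = data.frame(start_s = starts, center_mpf = center_mpf,
                         power_ratio = ratios),
    peak_ratio = ratios[k], peak_time_mpf = center_mpf[k]
  ), class = "swt_result")
}

#' @export
print.swt_result <- function(x, ...) {
  cat(sprintf("<swt_result> %d windows, peak ratio %.3f at %.1f mpf\n",
              nrow(x$windows), x$peak_ratio, x$peak_time_mpf))
  invisible(x)
}

shuffle_pairs <- function(x) {
  n <- length(x)
  np <- n %/% 2L
  pairs <- matrix(x[seq_len(2L * np)], nrow = 2L)
  ord <- sample.int(np)
  out <- as.vector(pairs[, ord])
  if (n %% 2L) out <- c(out, x[n])
  out
}

#' Shuffled baseline for peak SWT power ratios
#'
#' Each scan window is partitioned into consecutive non-overlapping pairs
#' of neighboring values; the order of the pairs is randomly permuted
#' (within-pair order preserved) before the Fourier transform, which
#' destroys slow (20-40 mHz) structure while preserving one-lag texture.
#' The peak SWT ratio of the shuffled profile is recorded per shuffle.
#'
#' @param profile A [twitch_profile()].
#' @param n_shuffles Number of shuffles.
#' @param seed RNG seed.
#' @param ... Passed to the scan (window/step/band).
#' @return List: `peaks` (one per shuffle) and `mean` (the dashed-line
#'   baseline).
#' @export
shuffled_baseline <- function(profile, n_shuffles = 100L, seed = 1L,
                              window_s = 900L, step_s = 200L,
                              start_offset_s = 3600L, band = c(0.02, 0.04)) {
  x <- profile$tally
  x[profile$excluded] <- NA_real_
  x <- fill_missing(x)
  starts <- swt_window_starts(profile$onset_frame, profile$hatch_frame,
                              start_offset_s, window_s, step_s)
  if (!length(starts)) stop("no full window between onset + offset and hatch")
  peaks <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(b) {
      max(vapply(starts, function(s)
        swt_power_ratio(shuffle_pairs(x[s:(s + window_s - 1L)]),
                        band = band, window_s = window_s), numeric(1L)))
    }, numeric(1L))
  })
  list(peaks = peaks, mean = mean(peaks))
}

#' Continuous wavelet scalogram of a tally trace
#'
#' Frequency-domain continuous wavelet transform with an analytic Morlet
#' wavelet, evaluated over 1-100 mHz, for visualizing the temporal
#' structure of twitch profiles (the SWT band appears as a 20-40 mHz
#' ridge). Intended for inspection; the quantitative statistic is
#' [swt_power_ratio()].
#'
#' @param tally Tally series at 1 Hz.
#' @param freqs_mhz Analysis frequencies (mHz).
#' @param omega0 Morlet angular carrier (default 6).
#' @return List of class `scalogram`: `freq_mhz`, `time_s`, `magnitude`
#'   (frequencies x time).
#' @export
scalogram <- function(tally, freqs_mhz = exp(seq(log(1), log(100),
                                                 length.out = 64L)),
                      omega0 = 6) {
  x <- as.numeric(tally)
  n <- length(x)
  xf <- stats::fft(x - mean(x))
  w <- 2 * pi * (seq_len(n) - 1L) / n          # rad/sample, 1 Hz sampling
  w[w > pi] <- w[w > pi] - 2 * pi
  mag <- matrix(0, length(freqs_mhz), n)
  for (k in seq_along(freqs_mhz)) {
    f <- freqs_mhz[k] / 1000
    s <- omega0 / (2 * pi * f)
    psi <- numeric(n)
    posw <- w > 0
    psi[posw] <- pi^(-0.25) * exp(-0.5 * (s * w[posw] - omega0)^2) * sqrt(s)
    mag[k, ] <- Mod(stats::fft(xf * psi, inverse = TRUE)) / n
  }
  structure(list(freq_mhz = freqs_mhz, time_s = seq_len(n) - 1L,
                 magnitude = mag),
            class = "scalogram")
}
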