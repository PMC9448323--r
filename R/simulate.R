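#' Simulation configuration
#'
#' Collects the parameters of the synthetic-embryo generators. Defaults
#' encode the study conditions: a ~50 x 30 x 30 um eggshell (semiaxes 25,
#' 15, 15), 3 Hz posture imaging, flipping at 3.5 flips/min with
#' exponential transition durations of mean 7.21 s, a 20-40 mHz
#' slow-wave-twitch epoch about an hour before hatching, and detection
#' corruption comparable to the segmentation quality of the real pipeline
#' (sub-um jitter, a few percent missed nuclei, about one clutter point per
#' volume).
#'
#' @param seed Integer seed; every generator draws from its own stream
#'   derived from this seed and restores the caller's RNG state.
#' @param frame_rate_hz Volumes per second (3 for posture, 1 for
#'   twitch/calcium).
#' @param eggshell_semiaxes_um Ellipsoid semiaxes (x, y, z) in um.
#' @param phase_schedule Data frame with columns `phase` (one of
#'   `"flipping"`, `"inactive"`, `"mature"`), `start_mpf`, `end_mpf`;
#'   phases must be time-ordered and non-overlapping.
#' @param flip_rate_per_min Nominal flip rate during the flipping phase.
#' @param flip_duration_mean_s Mean of the exponential flip-transition
#'   duration (time between half-amplitude crossings).
#' @param swt_window_mpf Two-element window (mpf) of the SWT epoch.
#' @param swt_freq_mhz SWT oscillation frequency, in [20, 40] mHz.
#' @param detection_jitter_um Isotropic Gaussian detection jitter SD.
#' @param false_negative_rate Per-nucleus-per-frame drop probability.
#' @param false_positive_rate_per_frame Poisson mean of clutter points.
#' @param body_length_um Total body arc length (folded embryo, ~90 um).
#' @param lateral_offset_um Left/right nucleus offset from the midline.
#' @param flip_amplitude_um Dorsoventral excursion of a full coil.
#' @param wave_amplitude_um Amplitude of the mature travelling wave.
#' @param wave_freq_hz Undulation frequency of the mature wave.
#' @param translation_speed_um_s Speed of mature directed motion bouts.
#' @param swt_mod_depth Depth (0..1) of SWT speed/tally gating.
#' @param twitch_levels Mean tallies for the pre-onset, early-active,
#'   reduced and late-active twitch phases.
#' @param transient_peak Peak dR/R0 of simulated calcium transients.
#' @param transient_fwhm_s Full width at half maximum of a transient.
#' @param refractory_s Renewal-process refractory period between onsets.
#' @param calcium_noise_sd Additive dR/R0 noise SD.
#' @param speed_coupling 0..1 coupling of behavioral slowing to transients.
#' @param base_speed_um_s Cell speed outside transients.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       frame_rate_hz = 3,
                       eggshell_semiaxes_um = c(25, 15, 15),
                       phase_schedule = data.frame(
                         phase = c("flipping", "inactive", "mature"),
                         start_mpf = c(530, 600, 650),
                         end_mpf = c(600, 650, 800)),
                       flip_rate_per_min = 3.5,
                       flip_duration_mean_s = 7.21,
                       swt_window_mpf = c(690, 720),
                       swt_freq_mhz = 30,
                       detection_jitter_um = 0.5,
                       false_negative_rate = 0.05,
                       false_positive_rate_per_frame = 1,
                       body_length_um = 90,
                       lateral_offset_um = 2,
                       flip_amplitude_um = 8,
                       wave_amplitude_um = 5,
                       wave_freq_hz = 0.3,
                       translation_speed_um_s = 1,
                       swt_mod_depth = 0.9,
                       twitch_levels = c(pre = 8, active1 = 200,
                                         reduced = 60, active2 = 250),
                       transient_peak = 4,
                       transient_fwhm_s = 10,
                       refractory_s = 12,
                       calcium_noise_sd = 0.1,
                       speed_coupling = 1,
                       base_speed_um_s = 0.8) {
  ps <- phase_schedule
  stopifnot(all(c("phase", "start_mpf", "end_mpf") %in% names(ps)),
            all(ps$phase %in% c("flipping", "inactive", "mature")),
            all(ps$end_mpf > ps$start_mpf))
  if (nrow(ps) > 1L) {
    o <- order(ps$start_mpf)
    if (any(ps$start_mpf[o][-1L] < ps$end_mpf[o][-nrow(ps)]))
      stop("phase schedule must be non-overlapping and time-ordered")
    ps <- ps[o, ]
  }
  rates <- c(flip_rate_per_min, detection_jitter_um,
             false_positive_rate_per_frame, swt_freq_mhz, flip_duration_mean_s)
  stopifnot(all(is.finite(rates)), all(rates >= 0),
            all(eggshell_semiaxes_um > 0),
            false_negative_rate >= 0, false_negative_rate <= 1,
            swt_freq_mhz >= 20, swt_freq_mhz <= 40)
  structure(list(
    seed = as.integer(seed), frame_rate_hz = frame_rate_hz,
    eggshell_semiaxes_um = eggshell_semiaxes_um, phase_schedule = ps,
    flip_rate_per_min = flip_rate_per_min,
    flip_duration_mean_s = flip_duration_mean_s,
    swt_window_mpf = swt_window_mpf, swt_freq_mhz = swt_freq_mhz,
    detection_jitter_um = detection_jitter_um,
    false_negative_rate = false_negative_rate,
    false_positive_rate_per_frame = false_positive_rate_per_frame,
    body_length_um = body_length_um, lateral_offset_um = lateral_offset_um,
    flip_amplitude_um = flip_amplitude_um,
    wave_amplitude_um = wave_amplitude_um, wave_freq_hz = wave_freq_hz,
    translation_speed_um_s = translation_speed_um_s,
    swt_mod_depth = swt_mod_depth, twitch_levels = twitch_levels,
    transient_peak = transient_peak, transient_fwhm_s = transient_fwhm_s,
    refractory_s = refractory_s, calcium_noise_sd = calcium_noise_sd,
    speed_coupling = speed_coupling, base_speed_um_s = base_speed_um_s
  ), class = "sim_config")
}

ramanujan_circumference <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# Arc-length parameterization of the neutral midline track (an ellipse
# inset from the eggshell equator).
neutral_track <- function(config) {
  ea <- config$eggshell_semiaxes_um[1L] - 5
  eb <- config$eggshell_semiaxes_um[2L] - 4
  th <- seq(0, 2 * pi, length.out = 4096L)
  x <- ea * cos(th); y <- eb * sin(th)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  arc <- c(0, cumsum(seg))
  list(ea = ea, eb = eb, theta = th, arc = arc,
       circumference = arc[length(arc)])
}

track_point <- function(track, s) {
  s <- s %% track$circumference
  th <- stats::approx(track$arc, track$theta, xout = s)$y
  cbind(track$ea * cos(th), track$eb * sin(th))
}

track_tangent <- function(track, s) {
  s <- s %% track$circumference
  th <- stats::approx(track$arc, track$theta, xout = s)$y
  tg <- cbind(-track$ea * sin(th), track$eb * cos(th))
  tg / sqrt(rowSums(tg^2))
}

#' Simulate a flipping PC1 amplitude trace
#'
#' Generates the latent coiling amplitude of the flipping phase: a square
#' wave alternating between +1 and -1 with linear transitions. The flip
#' (transition) duration `d` is drawn from an exponential distribution and
#' is defined as the time between half-amplitude crossings, matching the
#' duration convention of [detect_flips()]; the full ramp therefore lasts
#' `2 d`. Flip starts follow a renewal process whose gap is sized so the
#' nominal flip rate is realized on average.
#'
#' @param duration_s Trace length (ignored when `n_flips` is given).
#' @param frame_rate Samples per second.
#' @param flip_rate_per_min Nominal flips per minute.
#' @param flip_duration_mean_s Mean transition duration.
#' @param n_flips Generate until this many flips instead of a fixed
#'   duration.
#' @param seed RNG seed.
#' @return List: `pc1` (amplitude series in [-1, 1]), `time_s`, `flips`
#'   (data frame of ground-truth transitions: `start_s`, `end_s`,
#'   `duration_s` between half-amplitude crossings, `direction`).
#' @export
simulate_flip_trace <- function(duration_s = 600, frame_rate = 3,
                                flip_rate_per_min = 3.5,
                                flip_duration_mean_s = 7.21,
                                n_flips = NULL, seed = 1L) {
  if (flip_rate_per_min <= 0) {
    tt <- seq(0, duration_s, by = 1 / frame_rate)
    return(list(pc1 = rep(1, length(tt)), time_s = tt,
                flips = data.frame(start_s = numeric(), end_s = numeric(),
                                   duration_s = numeric(),
                                   direction = character())))
  }
  gap_mean <- max(1, 60 / flip_rate_per_min - 2 * flip_duration_mean_s)
  with_seed(seed, {
    starts <- numeric(); durs <- numeric()
    t <- stats::rexp(1L, 1 / gap_mean)
    repeat {
      d <- stats::rexp(1L, 1 / flip_duration_mean_s)
      starts <- c(starts, t); durs <- c(durs, d)
      t <- t + 2 * d + stats::rexp(1L, 1 / gap_mean)
      if (is.null(n_flips)) { if (t > duration_s + 60) break }
      else if (length(starts) >= n_flips) break
    }
    total <- if (is.null(n_flips)) duration_s else t + 30
    tt <- seq(0, total, by = 1 / frame_rate)
    x <- numeric(length(tt))
    state <- 1
    x[] <- state
    for (k in seq_along(starts)) {
      t0 <- starts[k]; D <- 2 * durs[k]
      ramp <- tt >= t0 & tt < t0 + D
      x[ramp] <- state * (1 - 2 * (tt[ramp] - t0) / D)
      after <- tt >= t0 + D
      state <- -state
      x[after] <- state
    }
    flips <- data.frame(
      start_s = starts + durs / 2, end_s = starts + 1.5 * durs,
      duration_s = durs,
      direction = rep_len(c("dorsal->ventral", "ventral->dorsal"),
                          length(starts)))
    keep <- flips$end_s <= total
    list(pc1 = x, time_s = tt, flips = flips[keep, , drop = FALSE])
  })
}

phase_at_mpf <- function(schedule, mpf) {
  out <- rep("inactive", length(mpf))
  for (k in seq_len(nrow(schedule)))
    out[mpf >= schedule$start_mpf[k] & mpf < schedule$end_mpf[k]] <-
      schedule$phase[k]
  out
}

#' Simulate a ground-truth posture sequence
#'
#' Builds a 20-nucleus lattice trajectory confined to the eggshell. The
#' body midline runs along an ellipse inset from the eggshell equator,
#' with stations at fixed arc-length spacing and left/right nuclei offset
#' from the midline. Latent amplitudes drive dorsoventral displacement
#' modes: the flipping phase is a square-wave coiling mode with smooth
#' (linear-ramp) transitions; the mature phase is a travelling wave
#' (phase-shifted second/third modes) plus bout-structured translation
#' along the track, gated multiplicatively at the SWT frequency inside the
#' SWT window; the inactive phase is quiet. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `embryo_truth`: `states` (a
#'   `posture_sequence`), `latents` (frames x 4), `phase` (per frame),
#'   `flips` (ground-truth flip table, frame units), `frame_rate`,
#'   `config`.
#' @export
simulate_posture_sequence <- function(config = sim_config()) {
  track <- neutral_track(config)
  if (config$body_length_um > track$circumference)
    stop("body length exceeds eggshell capacity (",
         round(track$circumference, 1), " um)")
  fr <- config$frame_rate_hz
  sched <- config$phase_schedule
  t0_mpf <- min(sched$start_mpf)
  t1_mpf <- max(sched$end_mpf)
  tt <- seq(0, (t1_mpf - t0_mpf) * 60, by = 1 / fr)
  mpf <- t0_mpf + tt / 60
  TT <- length(tt)
  phase <- phase_at_mpf(sched, mpf)

  latents <- matrix(0, TT, 4L,
                    dimnames = list(NULL, c("a1", "a2", "a3", "a4")))
  flips <- data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), direction = character())
  with_seed(config$seed, {
    # flipping-phase coiling amplitude
    flip_frames <- which(phase == "flipping")
    if (length(flip_frames)) {
      dur <- (length(flip_frames)) / fr
      ft <- simulate_flip_trace(duration_s = dur, frame_rate = fr,
                                flip_rate_per_min = config$flip_rate_per_min,
                                flip_duration_mean_s = config$flip_duration_mean_s,
                                seed = stats::runif(1L, 1, 2^30))
      n <- min(length(flip_frames), length(ft$pc1))
      latents[flip_frames[seq_len(n)], 1L] <- ft$pc1[seq_len(n)]
      off_s <- tt[flip_frames[1L]]
      flips <- ft$flips
      flips$start_s <- flips$start_s + off_s
      flips$end_s <- flips$end_s + off_s
    }
    # mature-phase travelling wave
    mat <- phase == "mature"
    latents[mat, 2L] <- sin(2 * pi * config$wave_freq_hz * tt[mat])
    latents[mat, 3L] <- cos(2 * pi * config$wave_freq_hz * tt[mat])
    latents[, 4L] <- 0.05 * stats::rnorm(TT)

    # translation bouts (mature phase), SWT-gated inside the SWT window
    v <- numeric(TT)
    if (any(mat) && config$translation_speed_um_s > 0) {
      t <- min(tt[mat])
      tmax <- max(tt[mat])
      dirn <- 1
      while (t < tmax) {
        move_d <- stats::rexp(1L, 1 / 10)
        pause_d <- stats::rexp(1L, 1 / 5)
        v[tt >= t & tt < t + move_d & mat] <- dirn * config$translation_speed_um_s
        t <- t + move_d + pause_d
        dirn <- -dirn
      }
    }
    swt <- mpf >= config$swt_window_mpf[1L] & mpf < config$swt_window_mpf[2L]
    gate <- rep(1, TT)
    f_swt <- config$swt_freq_mhz / 1000
    if (any(swt))
      gate[swt] <- 1 - config$swt_mod_depth *
        (1 + cos(2 * pi * f_swt * (tt[swt] - min(tt[swt])))) / 2
    v <- v * gate
    s0 <- cumsum(v) / fr

    # geometry
    u <- (0:9) / 9
    m1 <- sin(pi * u); m2 <- sin(2 * pi * u); m3 <- cos(2 * pi * u)
    m4 <- sin(3 * pi * u)
    ell <- config$body_length_um / 9
    ids <- seam_cell_ids()
    ax <- config$eggshell_semiaxes_um
    states <- vector("list", TT)
    amp1 <- config$flip_amplitude_um
    amp2 <- config$wave_amplitude_um
    for (t in seq_len(TT)) {
      s_i <- s0[t] + (0:9) * ell
      base <- track_point(track, s_i)
      tang <- track_tangent(track, s_i)
      nrm <- cbind(-tang[, 2L], tang[, 1L])  # in-plane normal
      z <- amp1 * latents[t, 1L] * m1 +
        amp2 * (latents[t, 2L] * m2 + latents[t, 3L] * m3) +
        0.5 * latents[t, 4L] * m4
      mid <- cbind(base, z)
      off <- config$lateral_offset_um
      left <- mid + off * cbind(nrm, 0)
      right <- mid - off * cbind(nrm, 0)
      pos <- rbind(left, right)
      rownames(pos) <- ids
      # eggshell containment: radial clamp with a small margin
      val <- (pos[, 1L] / ax[1L])^2 + (pos[, 2L] / ax[2L])^2 +
        (pos[, 3L] / ax[3L])^2
      vmax <- max(val)
      if (vmax > 0.98) pos <- pos * sqrt(0.98 / vmax)
      states[[t]] <- posture_state(pos, frame = t - 1L,
                                   time_s = tt[t], frame_rate = fr)
    }
    flips$start_frame <- round(flips$start_s * fr) + 1L
    flips$end_frame <- round(flips$end_s * fr) + 1L
    structure(list(states = posture_sequence(states, frame_rate = fr),
                   latents = latents, phase = phase, flips = flips,
                   time_s = tt, mpf = mpf, frame_rate = fr, config = config),
              class = "embryo_truth")
  })
}

#' @export
print.embryo_truth <- function(x, ...) {
  cat(sprintf("<embryo_truth> %d frames at %g Hz (%s), %d flips\n",
              length(x$states), x$frame_rate,
              paste(unique(x$phase), collapse = "/"), nrow(x$flips)))
  invisible(x)
}

uniform_in_ellipsoid <- function(n, ax) {
  out <- matrix(NA_real_, 0L, 3L)
  while (nrow(out) < n) {
    cand <- cbind(stats::runif(2L * n + 8L, -ax[1L], ax[1L]),
                  stats::runif(2L * n + 8L, -ax[2L], ax[2L]),
                  stats::runif(2L * n + 8L, -ax[3L], ax[3L]))
    keep <- (cand[, 1L] / ax[1L])^2 + (cand[, 2L] / ax[2L])^2 +
      (cand[, 3L] / ax[3L])^2 <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Corrupt ground-truth postures into detection sets
#'
#' Each true nucleus position is perturbed by isotropic Gaussian jitter,
#' dropped with the configured false-negative probability, and
#' Poisson-distributed clutter points are added uniformly inside the
#' eggshell. Detections are shuffled within each frame. The provenance map
#' records, for every detection, the source nucleus id or `"CLUTTER"`.
#'
#' @param truth An `embryo_truth` from [simulate_posture_sequence()], or a
#'   `posture_sequence`.
#' @param config A [sim_config()] (jitter/FN/FP rates and seed).
#' @return Object of class `detection_sequence`: `detections` (list of
#'   m x 3 matrices) and `provenance` (list of character vectors).
#' @export
corrupt_detections <- function(truth, config = sim_config()) {
  states <- if (inherits(truth, "embryo_truth")) truth$states else truth
  if (!length(states)) stop("empty truth sequence")
  ax <- config$eggshell_semiaxes_um
  with_seed(config$seed + 99991L, {
    det <- vector("list", length(states))
    prov <- vector("list", length(states))
    for (t in seq_along(states)) {
      pos <- states[[t]]$positions
      ids <- rownames(pos)
      keep <- stats::runif(nrow(pos)) >= config$false_negative_rate
      pts <- pos[keep, , drop = FALSE] +
        matrix(stats::rnorm(3L * sum(keep), sd = config$detection_jitter_um),
               ncol = 3L)
      lab <- ids[keep]
      ncl <- stats::rpois(1L, config$false_positive_rate_per_frame)
      if (ncl > 0L) {
        pts <- rbind(pts, uniform_in_ellipsoid(ncl, ax))
        lab <- c(lab, rep("CLUTTER", ncl))
      }
      ord <- sample.int(nrow(pts))
      rownames(pts) <- NULL
      det[[t]] <- pts[ord, , drop = FALSE]
      prov[[t]] <- lab[ord]
    }
    structure(list(detections = det, provenance = prov),
              class = "detection_sequence")
  })
}

#' @export
print.detection_sequence <- function(x, ...) {
  cat(sprintf("<detection_sequence> %d frames, %.1f detections/frame\n",
              length(x$detections),
              mean(vapply(x$detections, nrow, integer(1L)))))
  invisible(x)
}

twitch_envelope <- function(n_frames, onset_frame, hatch_frame, config) {
  mpf <- 430 + (seq_len(n_frames) - onset_frame) / 60
  lv <- config$twitch_levels
  mean_t <- rep(lv[["pre"]], n_frames)
  act <- seq_len(n_frames) >= onset_frame
  mean_t[act & mpf < 550] <- lv[["active1"]]
  mean_t[act & mpf >= 550 & mpf < 650] <- lv[["reduced"]]
  mean_t[act & mpf >= 650] <- lv[["active2"]]
  mean_t[seq_len(n_frames) >= hatch_frame] <- 0
  list(mean = mean_t, mpf = mpf)
}

#' Simulate a brightfield twitch tally trace
#'
#' Pre-onset noise stays below the onset criterion; after onset the tally
#' follows the three-phase envelope (active / reduced / active). Inside
#' the SWT window the tally is modulated sinusoidally at the SWT frequency
#' (multiplicative gating, emulating periodic pausing). Values are
#' integers in [0, 441], drawn binomially around the envelope.
#'
#' @param onset_frame,hatch_frame 1-based indices, onset < hatch.
#' @param config A [sim_config()].
#' @param n_frames Trace length (default `hatch_frame + 300`).
#' @return A [twitch_profile()] (onset/hatch left `NA` for the detectors);
#'   attribute `truth` holds the generating indices.
#' @export
simulate_twitch_trace <- function(onset_frame, hatch_frame,
                                  config = sim_config(), n_frames = NULL) {
  stopifnot(onset_frame < hatch_frame)
  if (is.null(n_frames)) n_frames <- hatch_frame + 300L
  env <- twitch_envelope(n_frames, onset_frame, hatch_frame, config)
  swt <- env$mpf >= config$swt_window_mpf[1L] &
    env$mpf < config$swt_window_mpf[2L]
  gate <- rep(1, n_frames)
  f <- config$swt_freq_mhz / 1000
  tt <- seq_len(n_frames) - 1
  if (any(swt))
    gate[swt] <- 1 - config$swt_mod_depth *
      (1 + cos(2 * pi * f * (tt[swt] - min(tt[swt])))) / 2
  p <- pmin(env$mean * gate / 441, 1)
  tally <- with_seed(config$seed + 4242L,
                     stats::rbinom(n_frames, 441L, p))
  out <- twitch_profile(tally, embryo_id = sprintf("sim-%d", config$seed))
  attr(out, "truth") <- list(onset_frame = onset_frame,
                             hatch_frame = hatch_frame,
                             swt_frames = which(swt))
  out
}

#' Simulate dual-channel calcium traces with motion coupling
#'
#' Transient onsets follow a stationary renewal process (refractory period
#' plus an exponential gap) with the requested mean inter-onset interval;
#' each transient is a trapezoidal dR/R0 pulse (1 s rise and fall) with
#' the configured peak and full width at half maximum. The compact support
#' (FWHM + 1 s) keeps successive transients separated by the refractory
#' period resolvable at the hysteresis thresholds even after the span-4
#' detection smoothing. mCherry is constant up to small
#' multiplicative noise; GCaMP is mCherry times the ratio. The cell's
#' random-walk speed drops toward zero during transients in proportion to
#' `config$speed_coupling`.
#'
#' @param n_embryos Number of embryos.
#' @param duration_s Trace length per embryo (>= 60 s), 1 Hz.
#' @param rate_spec Mean inter-onset interval in seconds (e.g. 40.3).
#' @param config A [sim_config()].
#' @return List: `traces` (list of [calcium_trace()]), `truth` (list with
#'   per-embryo ground-truth onset times).
#' @export
simulate_calcium_traces <- function(n_embryos, duration_s, rate_spec,
                                    config = sim_config()) {
  stopifnot(duration_s >= 60)
  refr <- config$refractory_s
  exp_mean <- max(rate_spec - refr, 0.5)
  W <- config$transient_fwhm_s + 1  # trapezoid support; FWHM = W - 1
  with_seed(config$seed + 777L, {
    traces <- vector("list", n_embryos)
    onsets_all <- vector("list", n_embryos)
    for (e in seq_len(n_embryos)) {
      t <- -5 * rate_spec
      onsets <- numeric()
      while (t < duration_s + 2 * W) {
        t <- t + refr + stats::rexp(1L, 1 / exp_mean)
        onsets <- c(onsets, t)
      }
      tt <- seq_len(duration_s) - 1
      x <- numeric(length(tt))
      for (t0 in onsets) {
        tau <- tt - t0
        inpulse <- tau >= 0 & tau <= W
        shape <- pmin(1, pmin(tau, W - tau))  # 1 s linear rise and fall
        x[inpulse] <- x[inpulse] +
          config$transient_peak * pmax(shape[inpulse], 0)
      }
      dr <- x + stats::rnorm(length(tt), sd = config$calcium_noise_sd)
      mch <- 100 * (1 + 0.01 * stats::rnorm(length(tt)))
      gc <- mch * (1 + dr)
      slow <- pmin(x / config$transient_peak, 1) * config$speed_coupling
      step <- matrix(stats::rnorm(3L * length(tt)), ncol = 3L)
      step <- step / sqrt(rowSums(step^2)) * config$base_speed_um_s * (1 - slow)
      pos <- apply(step, 2L, cumsum)
      traces[[e]] <- calcium_trace(time_s = tt, gcamp = gc, mcherry = mch,
                                   position_um = pos,
                                   embryo_id = sprintf("sim-%d", e))
      onsets_all[[e]] <- onsets[onsets >= 0 & onsets < duration_s]
    }
    list(traces = traces, truth = list(onsets = onsets_all))
  })
}

#' Simulate a small brightfield movie
#'
#' A dark ellipse (the embryo) on a bright background whose internal
#' texture toggles a specified number of box pixels per frame (each toggle
#' changes intensity by more than the tally threshold, so the designed
#' per-frame change count equals the expected tally). Hatching is rendered
#' as the ellipse vacating its position.
#'
#' @param n_frames Number of frames (1 Hz).
#' @param change_pixels Per-frame count of toggled box pixels (recycled).
#' @param hatch_frame Frame at which the embryo vacates, or `NA`.
#' @param img_size Square image side (default 64).
#' @param center Embryo center `c(row, col)`.
#' @param seed RNG seed for pixel selection.
#' @return List: `images` (list of matrices, counts), `center`, `truth`.
#' @export
simulate_brightfield_movie <- function(n_frames, change_pixels = 100L,
                                       hatch_frame = NA_integer_,
                                       img_size = 64L,
                                       center = c(32L, 32L), seed = 1L) {
  change_pixels <- rep_len(change_pixels, n_frames)
  bg <- 500; emb <- 200; delta <- 31
  base <- matrix(bg, img_size, img_size)
  rr <- row(base) - center[1L]
  cc <- col(base) - center[2L]
  inside <- (rr / 10)^2 + (cc / 9)^2 <= 1
  base[inside] <- emb
  half <- 10L
  box_idx <- which(abs(rr) <= half & abs(cc) <= half & inside)
  with_seed(seed, {
    raised <- rep(FALSE, length(box_idx))
    images <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      hatched <- !is.na(hatch_frame) && t >= hatch_frame
      img <- base
      if (hatched) {
        img[inside] <- bg
      } else if (t > 1L) {
        k <- min(change_pixels[t], length(box_idx))
        tog <- sample.int(length(box_idx), k)
        raised[tog] <- !raised[tog]
      }
      if (!hatched) img[box_idx[raised]] <- emb + delta
      images[[t]] <- img
    }
    list(images = images, center = center,
         truth = list(change_pixels = change_pixels,
                      hatch_frame = hatch_frame))
  })
}

#' Summaries of a brightfield movie around one embryo
#'
#' Computes the tally trace (21 x 21 box), the mean embryo-box intensity,
#' and the background-perimeter statistics (mean intensity and per-frame
#' counts of perimeter pixels changing by more than the background
#' threshold) from the 240-pixel outline of a 61 x 61 box.
#'
#' @param images List of image matrices.
#' @param center Embryo center `c(row, col)`.
#' @param change_threshold Tally threshold (25).
#' @param background_threshold Background change threshold (35).
#' @return List: `tally`, `embryo_mean`, `background_mean`,
#'   `background_changes`.
#' @export
summarize_brightfield <- function(images, center, change_threshold = 25,
                                  background_threshold = 35) {
  tally <- compute_tally_trace(images, center, change_threshold)
  half_in <- 10L
  half_out <- 30L
  dmn <- dim(images[[1L]])
  rr <- abs(row(images[[1L]]) - center[1L])
  cc <- abs(col(images[[1L]]) - center[2L])
  ring <- (rr == half_out & cc <= half_out) |
    (cc == half_out & rr <= half_out)
  box <- rr <= half_in & cc <= half_in
  if (center[1L] - half_out < 1L || center[1L] + half_out > dmn[1L] ||
      center[2L] - half_out < 1L || center[2L] + half_out > dmn[2L])
    stop("background perimeter exceeds image bounds")
  n <- length(images)
  embryo_mean <- vapply(images, function(im) mean(im[box]), numeric(1L))
  background_mean <- vapply(images, function(im) mean(im[ring]), numeric(1L))
  background_changes <- integer(n)
  for (t in seq_len(n)[-1L]) {
    background_changes[t] <-
      sum(abs(images[[t]][ring] - images[[t - 1L]][ring]) > background_threshold)
  }
  list(tally = tally, embryo_mean = embryo_mean,
       background_mean = background_mean,
       background_changes = background_changes)
}
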