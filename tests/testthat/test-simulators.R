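test_that("simulators are deterministic given the seed and leave the RNG alone", {
  cfg <- sim_config(seed = 5, phase_schedule = data.frame(
    phase = "flipping", start_mpf = 530, end_mpf = 530.5))
  set.seed(999)
  before <- runif(3)
  set.seed(999)
  a <- simulate_posture_sequence(cfg)
  b <- simulate_posture_sequence(cfg)
  expect_identical(a$latents, b$latents)
  expect_identical(a$states[[10]]$positions, b$states[[10]]$positions)
  expect_identical(runif(3), before)  # caller RNG stream untouched

  da <- corrupt_detections(a, cfg)
  db <- corrupt_detections(b, cfg)
  expect_identical(da$detections, db$detections)

  ta <- simulate_twitch_trace(100L, 2000L, cfg, n_frames = 2100L)
  tb <- simulate_twitch_trace(100L, 2000L, cfg, n_frames = 2100L)
  expect_identical(ta$tally, tb$tally)

  ca <- simulate_calcium_traces(2, 120, 40.3, cfg)
  cb <- simulate_calcium_traces(2, 120, 40.3, cfg)
  expect_identical(ca$traces[[2]]$gcamp, cb$traces[[2]]$gcamp)
})

test_that("ground-truth positions stay inside the eggshell ellipsoid", {
  cfg <- sim_config(seed = 3, phase_schedule = data.frame(
    phase = c("flipping", "mature"), start_mpf = c(530, 531),
    end_mpf = c(531, 532)))
  truth <- simulate_posture_sequence(cfg)
  ax <- cfg$eggshell_semiaxes_um
  for (s in truth$states) {
    val <- (s$positions[, 1] / ax[1])^2 + (s$positions[, 2] / ax[2])^2 +
      (s$positions[, 3] / ax[3])^2
    expect_lte(max(val), 1)
  }
})

test_that("degenerate configurations behave as documented", {
  expect_error(simulate_posture_sequence(sim_config(body_length_um = 200)),
               "capacity")
  expect_error(sim_config(phase_schedule = data.frame(
    phase = c("flipping", "inactive"), start_mpf = c(530, 520),
    end_mpf = c(560, 545))), "non-overlapping")
  expect_error(sim_config(false_negative_rate = 1.2))

  # zero-amplitude latents, no translation: rigid motionless posture
  cfg0 <- sim_config(seed = 2, flip_amplitude_um = 0, wave_amplitude_um = 0,
                     translation_speed_um_s = 0,
                     phase_schedule = data.frame(phase = "flipping",
                                                 start_mpf = 530,
                                                 end_mpf = 530.3))
  cfg0$flip_rate_per_min <- 0.0  # no flip events either
  still <- simulate_posture_sequence(cfg0)
  disp <- vapply(seq_along(still$states)[-1], function(t)
    max(abs(still$states[[t]]$positions - still$states[[t - 1]]$positions)),
    numeric(1))
  expect_lt(max(disp), 0.2)  # only the tiny fourth-mode jitter remains
  cfg0$seed <- 4L
  still2 <- simulate_posture_sequence(cfg0)
  expect_gt(length(still2$states), 10)
})

test_that("flipping-phase transition counts land in the Poisson band of the rate", {
  # 10 minutes at 3.5 flips/min: ground-truth transition count within the
  # 99.9% Poisson band of 35
  counts <- vapply(1:4, function(seed) {
    ft <- simulate_flip_trace(duration_s = 600, flip_rate_per_min = 3.5,
                              seed = seed)
    nrow(ft$flips)
  }, numeric(1))
  band <- qpois(c(0.0005, 0.9995), 35)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("detection corruption is calibrated and conserves provenance", {
  cfg <- sim_config(seed = 8, phase_schedule = data.frame(
    phase = "flipping", start_mpf = 530, end_mpf = 533),
    detection_jitter_um = 0.5, false_negative_rate = 0.05,
    false_positive_rate_per_frame = 2)
  truth <- simulate_posture_sequence(cfg)
  det <- corrupt_detections(truth, cfg)
  TT <- length(det$detections)
  expect_equal(TT, length(truth$states))

  # provenance partitions detections into nuclei + clutter
  for (t in c(1, 50, TT)) {
    expect_equal(length(det$provenance[[t]]), nrow(det$detections[[t]]))
    lab <- det$provenance[[t]]
    expect_true(all(lab %in% c(seam_cell_ids(), "CLUTTER")))
    expect_false(anyDuplicated(lab[lab != "CLUTTER"]) > 0)
  }

  # realized FN fraction within the binomial 99% band of 0.05
  n_nucleus_frames <- 20 * TT
  kept <- sum(vapply(det$provenance, function(p) sum(p != "CLUTTER"),
                     numeric(1)))
  dropped <- n_nucleus_frames - kept
  p <- 0.05
  band <- qbinom(c(0.005, 0.995), n_nucleus_frames, p)
  expect_gte(dropped, band[1])
  expect_lte(dropped, band[2])

  # realized clutter rate within the Poisson band of 2 per frame
  clutter <- vapply(det$provenance, function(p) sum(p == "CLUTTER"),
                    numeric(1))
  band_c <- qpois(c(0.005, 0.995), 2 * TT) / TT
  expect_gte(mean(clutter), band_c[1])
  expect_lte(mean(clutter), band_c[2])

  # identity case: no jitter, no drops, no clutter reproduces the truth
  cfg0 <- cfg
  cfg0$detection_jitter_um <- 0
  cfg0$false_negative_rate <- 0
  cfg0$false_positive_rate_per_frame <- 0
  det0 <- corrupt_detections(truth, cfg0)
  for (t in c(1, 30)) {
    m <- det0$detections[[t]]
    rownames(m) <- det0$provenance[[t]]
    expect_equal(m[seam_cell_ids(), ], truth$states[[t]]$positions,
                 tolerance = 1e-12)
  }
})

test_that("twitch traces stay integral, bounded and onset-detectable", {
  cfg <- sim_config(seed = 4)
  tp <- simulate_twitch_trace(500L, 500L + 250L * 60L, cfg)
  expect_true(all(tp$tally >= 0 & tp$tally <= 441))
  expect_true(all(tp$tally == round(tp$tally)))
  onset <- detect_onset(tp$tally)
  expect_lte(abs(onset - 500L), 16L)

  # an all-zero envelope never triggers the onset criterion
  cfg0 <- sim_config(seed = 4, twitch_levels = c(pre = 0, active1 = 0,
                                                 reduced = 0, active2 = 0))
  tp0 <- simulate_twitch_trace(500L, 5000L, cfg0, n_frames = 6000L)
  expect_true(is.na(detect_onset(tp0$tally)))
})

test_that("calcium generator respects rate, coupling and onset statistics", {
  # mean interval 40 s over 300 s: about 7.5 true onsets per embryo
  sim <- simulate_calcium_traces(40, 300, 40, sim_config(seed = 11))
  mean_onsets <- mean(lengths(sim$truth$onsets))
  expect_equal(mean_onsets, 7.5, tolerance = 0.15)

  # transient rate 0 (an interval far beyond the trace) yields no events
  quiet <- simulate_calcium_traces(3, 120, 1e7, sim_config(seed = 12))
  for (tr in quiet$traces) {
    tr <- compute_dr_over_r0(tr)
    expect_equal(nrow(detect_transients(tr)), 0L)
  }

  # coupling 0: |r| between speed and dR/R0 below 0.1 at n = 300
  un <- simulate_calcium_traces(1, 300, 40.3,
                                sim_config(seed = 13, speed_coupling = 0))
  tr <- compute_dr_over_r0(un$traces[[1]])
  spd <- sqrt(rowSums(diff(tr$position_um)^2))
  expect_lt(abs(cor(spd, tr$dr_over_r0[-1])), 0.1)
})

test_that("brightfield movies render texture, hatch and background summaries", {
  mv <- simulate_brightfield_movie(400, change_pixels = 150,
                                   hatch_frame = 300L, seed = 5)
  s <- summarize_brightfield(mv$images, mv$center)
  expect_true(all(s$tally[2:299] == 150))
  expect_true(all(s$tally[302:400] == 0))
  hatch <- detect_hatch(s$embryo_mean, s$background_mean)
  expect_lte(abs(hatch - 300L), 16L)
  expect_false(any(build_exclusion_mask(s$background_changes)))
  # onset on the same series
  expect_lte(abs(detect_onset(s$tally) - 2L), 16L)
})
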