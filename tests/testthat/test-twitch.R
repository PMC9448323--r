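test_that("tally counts exactly the box pixels changed beyond threshold", {
  mv <- simulate_brightfield_movie(30, change_pixels = 0, seed = 1)
  expect_true(all(compute_tally_trace(mv$images, mv$center) == 0))

  mv200 <- simulate_brightfield_movie(30, change_pixels = 200, seed = 2)
  tally <- compute_tally_trace(mv200$images, mv200$center)
  expect_equal(tally[1], 0L)
  expect_true(all(tally[-1] == 200L))

  # direct per-pixel oracle on a random movie
  mvr <- simulate_brightfield_movie(10, change_pixels = c(0, 5, 40, 12, 0,
                                                          77, 3, 160, 9, 1),
                                    seed = 3)
  tally_r <- compute_tally_trace(mvr$images, mvr$center)
  half <- 10L
  rows <- (mvr$center[1] - half):(mvr$center[1] + half)
  cols <- (mvr$center[2] - half):(mvr$center[2] + half)
  for (t in 2:10) {
    expect_equal(tally_r[t],
                 sum(abs(mvr$images[[t]][rows, cols] -
                           mvr$images[[t - 1]][rows, cols]) > 25))
  }

  expect_error(compute_tally_trace(mvr$images, c(3, 3)), "bounds")
})

test_that("onset detection crosses at the smoothed 120-pixel criterion", {
  tally <- c(rep(0, 999), rep(200, 600))
  onset <- detect_onset(tally)
  # centered 30-frame mean of a step crosses 120 when 60% of the window is
  # high: analytic crossing within half a window of the step
  expect_lte(abs(onset - 1000L), 15L)
  expect_true(is.na(detect_onset(rep(100, 500))))
  expect_equal(detect_onset(rep(441, 100)), 1L)
})

test_that("hatch detection uses the smoothed signal-to-background ratio", {
  emb <- c(rep(250, 499), rep(500, 301))
  bg <- rep(500, 800)
  expect_lte(abs(detect_hatch(emb, bg) - 500L), 16L)
  expect_true(is.na(detect_hatch(rep(250, 300), rep(500, 300))))
  expect_warning(h <- detect_hatch(rep(500, 300), rep(500, 300)),
                 "criterion")
  expect_equal(h, 1L)
  expect_error(detect_hatch(emb, rep(0, 800)), "positive")
})

test_that("exclusion mask uses a strict threshold on smoothed background changes", {
  expect_false(any(build_exclusion_mask(rep(0, 400))))
  # hatchling crossing: 60 s of 100 changed pixels
  bgc <- c(rep(0, 200), rep(100, 60), rep(0, 200))
  mask <- build_exclusion_mask(bgc)
  expect_true(all(mask[215:245]))
  expect_false(any(mask[1:170]))
  expect_false(any(mask[300:460]))
  # smoothed count exactly 40 is NOT excluded
  expect_false(any(build_exclusion_mask(rep(40, 300))))
  expect_true(all(build_exclusion_mask(rep(41, 300))))
})

test_that("gap filling duplicates the preceding interval in reverse", {
  x <- c(5, 1, 2, 3, NA, NA, NA, 9)
  expect_equal(fill_missing(x), c(5, 1, 2, 3, 3, 2, 1, 9))
  expect_identical(fill_missing(1:10 * 1.0), 1:10 * 1.0)
  # two gaps fill independently, the second may draw on filled values
  y <- c(1, 2, NA, 7, 8, NA, NA, 3)
  expect_equal(fill_missing(y), c(1, 2, 2, 7, 8, 8, 7, 3))
  expect_error(fill_missing(c(NA, 1, 2)), "preceding")
  expect_error(fill_missing(c(1, NA, NA, 4)), "preceding")
})

test_that("SWT power ratio matches Parseval bookkeeping on known signals", {
  tt <- 0:899
  pure <- sin(2 * pi * 0.03 * tt)  # 27 cycles in 900 s: exact bin
  expect_gt(swt_power_ratio(pure), 0.99)
  expect_error(swt_power_ratio(pure[1:800]), "900")
  expect_error(swt_power_ratio(replace(pure, 3, NA)), "missing")

  # Parseval: total spectral power equals window energy
  set.seed(8)
  x <- rnorm(900)
  expect_equal(sum(Mod(fft(x))^2) / 900, sum(x^2), tolerance = 1e-9)

  # white noise: expected ratio ~ band-bin fraction 19/451
  ratios <- replicate(150, swt_power_ratio(rnorm(900)))
  expect_equal(mean(ratios), 19 / 451, tolerance = 0.15)

  # mixture against a direct DFT-sum oracle
  mix <- 50 + 10 * sin(2 * pi * 0.03 * tt) + rnorm(900)
  k <- 0:899
  Y <- vapply(k, function(kk)
    sum(mix * exp(-2i * pi * kk * tt / 900)), complex(1))
  f <- k / 900
  oracle <- sum(Mod(Y[f >= 0.02 - 1e-12 & f <= 0.04 + 1e-12])^2) /
    sum(Mod(Y[f <= 0.5 + 1e-12])^2)
  expect_equal(swt_power_ratio(mix), oracle, tolerance = 1e-12)
})

test_that("the SWT scan localizes an oscillatory epoch and sizes its window grid", {
  # window grid arithmetic for a 4 h onset-to-hatch span
  starts <- wormembryo:::swt_window_starts(1L, 14400L, 3600L, 900L, 200L)
  expect_length(starts, floor((14400 - 3600 - 900) / 200) + 1L)

  # 30 mHz modulation restricted to minutes 240-255 after onset
  cfg <- sim_config(seed = 6, swt_window_mpf = c(670, 685))
  onset <- 200L
  hatch <- onset + 300L * 60L
  tp <- simulate_twitch_trace(onset, hatch, cfg)
  tp$onset_frame <- detect_onset(tp$tally)
  tp$hatch_frame <- hatch
  res <- scan_peak_swt(tp)
  expect_true(all(res$windows$power_ratio >= 0 &
                    res$windows$power_ratio <= 1))
  # peak window (center reported) overlaps the modulated epoch
  expect_gte(res$peak_time_mpf, 670 - 7.5 - 200 / 60)
  expect_lte(res$peak_time_mpf, 685 + 7.5 + 200 / 60)
  expect_gt(res$peak_ratio, 2 * 19 / 451)

  # without any modulation the detrended peak sits at the white-noise floor
  cfg0 <- sim_config(seed = 7, swt_mod_depth = 0)
  tp0 <- simulate_twitch_trace(onset, hatch, cfg0)
  tp0$onset_frame <- detect_onset(tp0$tally)
  tp0$hatch_frame <- hatch
  res0 <- scan_peak_swt(tp0, detrend = TRUE)
  expect_lt(res0$peak_ratio, 0.12)
})

test_that("pair-block shuffling preserves values but destroys the SWT band", {
  set.seed(12)
  x <- rnorm(900)
  sh <- wormembryo:::shuffle_pairs(x)
  expect_equal(sort(sh), sort(x))
  pairs_in <- split(x, rep(1:450, each = 2))
  pairs_out <- split(sh, rep(1:450, each = 2))
  expect_true(all(vapply(pairs_out, function(p)
    any(vapply(pairs_in, identical, logical(1), p)), logical(1))))

  # constant trace: baseline equals the unshuffled ratio
  cfg <- sim_config(seed = 3)
  const <- twitch_profile(rep(200, 7000), onset_frame = 10L,
                          hatch_frame = 6900L)
  base <- shuffled_baseline(const, n_shuffles = 5, seed = 1)
  expect_equal(base$peaks, rep(scan_peak_swt(const)$peak_ratio, 5))

  # strong 30 mHz band collapses under shuffling
  tt <- 0:6999
  osc <- twitch_profile(round(200 + 150 * sin(2 * pi * 0.03 * tt)),
                        onset_frame = 10L, hatch_frame = 6900L)
  peak <- scan_peak_swt(osc, detrend = TRUE)$peak_ratio
  shuf <- shuffled_baseline(osc, n_shuffles = 10, seed = 2)
  shuf_peak <- mean(shuf$peaks)
  expect_lt(shuf_peak, 0.2 * peak)
})

test_that("the scalogram shows the expected time-frequency ridges", {
  tt <- 0:1999
  sc30 <- scalogram(sin(2 * pi * 0.03 * tt))
  ridge <- sc30$freq_mhz[apply(sc30$magnitude[, 500:1500], 2, which.max)]
  expect_lt(max(abs(ridge - 30)), 5)

  # chirp 10 -> 50 mHz: ridge frequency rises monotonically on average
  f0 <- 0.010; f1 <- 0.050
  inst <- f0 + (f1 - f0) * tt / max(tt)
  chirp <- sin(2 * pi * cumsum(inst))
  scc <- scalogram(chirp)
  mid <- 300:1700
  ridge_c <- scc$freq_mhz[apply(scc$magnitude[, mid], 2, which.max)]
  slope <- coef(lm(ridge_c ~ mid))[2]
  expect_gt(slope, 0)

  # white noise: the SWT band does not dominate, unlike the pure tone
  set.seed(4)
  scn <- scalogram(rnorm(2000))
  band <- scn$freq_mhz >= 25 & scn$freq_mhz <= 35
  dominance <- function(sc) mean(sc$magnitude[band, mid]) /
    mean(sc$magnitude[, mid])
  expect_gt(dominance(sc30), 3)
  expect_lt(dominance(scn), 2)
})
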