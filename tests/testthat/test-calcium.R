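make_blob_volume <- function(centers, peaks, sigmas, dims = c(40, 40, 3),
                             background = 100) {
  g <- array(background, dims)
  m <- array(background, dims)
  for (k in seq_along(peaks)) {
    cy <- centers[[k]][1]; cx <- centers[[k]][2]; cz <- centers[[k]][3]
    for (z in seq_len(dims[3])) {
      zf <- exp(-((z - cz)^2) / 2)
      r2 <- outer((seq_len(dims[1]) - cy)^2, (seq_len(dims[2]) - cx)^2, "+")
      m[, , z] <- m[, , z] + peaks[k] * zf * exp(-r2 / (2 * sigmas[k]^2))
    }
  }
  g <- m * 1.5  # GCaMP proportional to mCherry here
  list(gcamp = g, mcherry = m)
}

test_that("cell localization finds the filtered mCherry maximum", {
  vol <- make_blob_volume(list(c(20, 25, 2)), peaks = 300, sigmas = 3)
  tr <- extract_cell_trace(list(vol), voxel_um = c(0.5, 0.5, 2))
  expect_true(tr$valid[1])
  expect_equal(unname(tr$position_um[1, ]), c(19, 24, 1) * c(0.5, 0.5, 2),
               tolerance = 1.01)  # +/- 1 px in each axis

  # a dimmer but broader blob outcompetes a bright single-pixel spike
  # after sigma = 5 filtering; verify against a direct kernel-sum oracle
  sharp <- array(100, c(40, 40, 1)); sharp[10, 10, 1] <- 100 + 500
  broad_c <- c(30, 30)
  r2 <- outer((1:40 - broad_c[1])^2, (1:40 - broad_c[2])^2, "+")
  broad <- 150 * exp(-r2 / (2 * 4^2))
  vol2 <- list(gcamp = sharp + array(broad, c(40, 40, 1)),
               mcherry = sharp + array(broad, c(40, 40, 1)))
  tr2 <- extract_cell_trace(list(vol2), sigma = 5)
  expect_equal(unname(tr2$position_um[1, 1:2]), broad_c - 1, tolerance = 2.01)
  # oracle: the filtered response at the two candidate centers
  kern <- dnorm(-15:15, sd = 5); kern <- kern / sum(kern)
  K2 <- outer(kern, kern)
  img <- pmax(vol2$mcherry[, , 1] - 100, 0)
  resp <- function(cy, cx) {
    rows <- pmin(pmax(cy + (-15:15), 1), 40)
    cols <- pmin(pmax(cx + (-15:15), 1), 40)
    sum(K2 * img[rows, cols])
  }
  expect_gt(resp(broad_c[1], broad_c[2]), resp(10, 10))

  # featureless volume flags the frame invalid
  flat <- list(gcamp = array(100, c(20, 20, 2)),
               mcherry = array(100, c(20, 20, 2)))
  tr3 <- extract_cell_trace(list(flat))
  expect_false(tr3$valid[1])
})

test_that("dR/R0 uses the 10th-percentile baseline exactly", {
  # constant ratio: R0 = R everywhere, dR/R0 = 0
  tr <- calcium_trace(0:9, gcamp = rep(300, 10), mcherry = rep(100, 10))
  expect_equal(compute_dr_over_r0(tr)$dr_over_r0, rep(0, 10))

  # designed 10-point trace against hand arithmetic (linear-interpolation
  # percentile: R0 = R_(1) + 0.9 (R_(2) - R_(1)))
  R <- c(1.0, 1.1, 1.4, 2.0, 3.0, 4.0, 2.5, 1.2, 1.05, 1.6)
  tr2 <- calcium_trace(0:9, gcamp = R * 50, mcherry = rep(50, 10))
  tr2 <- compute_dr_over_r0(tr2)
  Rs <- sort(R)
  r0_hand <- Rs[1] + 0.9 * (Rs[2] - Rs[1])
  expect_equal(tr2$r0, r0_hand)
  expect_equal(tr2$dr_over_r0, (R - r0_hand) / r0_hand)
  # a frame at twice the baseline ratio reads 1.0
  tr3 <- compute_dr_over_r0(calcium_trace(0:9, gcamp = c(rep(50, 9), 100),
                                          mcherry = rep(50, 10)))
  expect_equal(tr3$dr_over_r0[10], 1, tolerance = 1e-12)

  expect_error(compute_dr_over_r0(calcium_trace(0:2, c(1, 2, 3), c(1, 0, 1))),
               "positive")
})

test_that("transient detection opens/closes with hysteresis and no retrigger", {
  # one clean event
  x <- c(rep(0, 10), 1, 3, 4, 4, 3, 2, 1.2, 0.5, rep(0, 10))
  ev <- detect_transients(x, smooth_span = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_frame, 12L)
  expect_equal(ev$peak_amplitude, 4)

  # dip to 1.6 (between thresholds) does not retrigger
  x2 <- c(rep(0, 5), 2.5, 3.5, 1.6, 1.7, 3.0, 1.0, rep(0, 5))
  ev2 <- detect_transients(x2, smooth_span = 1)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$offset_frame, 11L)

  # half-peak width via interpolated crossings: symmetric triangle pulse
  tri <- c(rep(0, 5), seq(0, 4, by = 0.5), seq(3.5, 0, by = -0.5), rep(0, 5))
  ev3 <- detect_transients(tri, smooth_span = 1)
  # crossings of 2 on the way up and down of a slope 0.5/s: width 8 s
  expect_equal(ev3$duration_s, 8, tolerance = 1e-9)

  expect_error(detect_transients(x, onset_thr = 1, offset_thr = 1.5),
               "exceed")

  # event count is invariant to noise below half the hysteresis margin
  set.seed(31)
  clean <- rep(0, 400)
  for (t0 in c(50, 150, 250, 350)) clean[t0 + 0:10] <-
    4 * sin(pi * (0:10) / 10)^2 * 2
  noisy <- clean + runif(400, -0.12, 0.12)
  expect_equal(nrow(detect_transients(noisy)), nrow(detect_transients(clean)))
})

test_that("about a tenth of dR/R0 samples sit below zero by construction", {
  sim <- simulate_calcium_traces(5, 300, 40.3, sim_config(seed = 9))
  for (tr in sim$traces) {
    tr <- compute_dr_over_r0(tr)
    expect_gte(mean(tr$dr_over_r0 < 0), 0.05)
    expect_lte(mean(tr$dr_over_r0 < 0), 0.15)
  }
})

test_that("simulated transient rates are recovered within 10 percent", {
  for (rate_mhz in c(10, 25, 50)) {
    interval <- 1000 / rate_mhz
    sim <- simulate_calcium_traces(40, 300, interval,
                                   sim_config(seed = 100 + rate_mhz))
    detected <- vapply(sim$traces, function(tr)
      nrow(detect_transients(compute_dr_over_r0(tr))), numeric(1))
    rate <- mean(detected) / 300 * 1000
    expect_equal(rate, rate_mhz, tolerance = 0.10)
  }
})

test_that("quiescence bouts require 3 s at or below 0.5 um/s", {
  still10 <- rbind(matrix(seq(0, 10, length.out = 11), 11, 3),
                   matrix(5 + seq(0, 10, length.out = 11)[-1] * 0, 10, 3))
  # explicit construction: 10 moving seconds then 10 still seconds
  pos <- apply(rbind(matrix(1, 10, 3), matrix(0, 10, 3)), 2, cumsum)
  q <- detect_quiescence(pos)
  expect_equal(nrow(q), 1L)
  expect_equal(q$duration_s, 10)

  pos2 <- apply(rbind(matrix(1, 10, 3), matrix(0, 2, 3),
                      matrix(1, 10, 3)), 2, cumsum)
  expect_equal(nrow(detect_quiescence(pos2)), 0L)

  # designed still intervals inside a random walk recovered within 1 s
  set.seed(6)
  steps <- matrix(rnorm(300 * 3), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2))  # 1 um/s: always moving
  steps[100:119, ] <- 0
  steps[200:204, ] <- 0
  q2 <- detect_quiescence(apply(steps, 2, cumsum))
  expect_equal(nrow(q2), 2L)
  expect_equal(q2$duration_s, c(20, 5), tolerance = 0.10)
})

test_that("event alignment centers the behavioral dip at the half-peak onset", {
  sim <- simulate_calcium_traces(6, 300, 40.3, sim_config(seed = 15))
  traces <- lapply(sim$traces, compute_dr_over_r0)
  events <- lapply(traces, detect_transients)
  al <- align_to_transient_onset(traces, events)
  expect_equal(al$time_s, -30:60)
  expect_gt(nrow(al$speed), 10)
  dip <- al$time_s[which.min(al$mean$speed)]
  expect_lte(abs(dip), 5)

  # uncoupled simulation: no comparable dip
  sim0 <- simulate_calcium_traces(6, 300, 40.3,
                                  sim_config(seed = 15, speed_coupling = 0))
  traces0 <- lapply(sim0$traces, compute_dr_over_r0)
  al0 <- align_to_transient_onset(traces0, lapply(traces0, detect_transients))
  depth <- function(a) 1 - min(a$mean$speed) / median(a$mean$speed)
  expect_gt(depth(al), 0.5)
  expect_lt(depth(al0), 0.2)

  # identical synthetic events: aligned mean equals any single event
  tr1 <- traces[[1]]
  al1 <- align_to_transient_onset(list(tr1, tr1), list(events[[1]], events[[1]]))
  expect_equal(al1$mean$gcamp, colMeans(al1$gcamp))
})

test_that("hierarchical bootstrap matches the two-level analytic standard error", {
  # degenerate: identical constants -> zero SD
  mat <- matrix(3, 12, 5)
  hb0 <- hierarchical_bootstrap(mat, rep(letters[1:3], each = 4),
                                n_boot = 50, seed = 2)
  expect_equal(hb0$sd, rep(0, 5))
  expect_warning(hierarchical_bootstrap(mat, rep("a", 12), n_boot = 5),
                 "single embryo")

  set.seed(12)
  n_emb <- 20L; m_ev <- 10L
  sb <- 1.0; se <- 2.0
  emb_eff <- rnorm(n_emb, sd = sb)
  y <- matrix(rep(emb_eff, each = m_ev), ncol = 1) +
    matrix(rnorm(n_emb * m_ev, sd = se), ncol = 1)
  ids <- rep(seq_len(n_emb), each = m_ev)
  hb <- hierarchical_bootstrap(y, ids, n_boot = 2000, seed = 3)
  analytic <- sqrt(sb^2 / n_emb + se^2 / (n_emb * m_ev))
  expect_equal(hb$sd, analytic, tolerance = 0.15)

  # fixed seed reproduces the replicate set
  hb2 <- hierarchical_bootstrap(y, ids, n_boot = 200, seed = 9)
  hb3 <- hierarchical_bootstrap(y, ids, n_boot = 200, seed = 9)
  expect_identical(hb2, hb3)
})

test_that("stimulus trials are categorized by RIS state with an inclusive onset", {
  sim <- simulate_calcium_traces(1, 300, 40.3, sim_config(seed = 22))
  tr <- compute_dr_over_r0(sim$traces[[1]])
  ev <- detect_transients(tr)
  expect_gt(nrow(ev), 2)

  on_time <- ev$onset_frame[2] - 1 + 1  # one second after event onset
  expect_equal(categorize_stimulus_trials(ev, on_time, tr)$label, "RIS_on")
  # exactly at the onset sample: inclusive rule
  expect_equal(categorize_stimulus_trials(ev, ev$onset_frame[2] - 1, tr)$label,
               "RIS_on")
  # midway between two events
  gap_mid <- floor((ev$offset_frame[1] + ev$onset_frame[2]) / 2)
  expect_equal(categorize_stimulus_trials(ev, gap_mid - 1, tr)$label,
               "RIS_off")
  res <- categorize_stimulus_trials(ev, 100, tr)
  expect_equal(res$windows$window, c("pre", "stim", "post"))
  expect_error(categorize_stimulus_trials(ev, 1e5, tr), "outside")
})

test_that("ALA neurite thresholds work through the same detector", {
  set.seed(3)
  x <- rep(0, 200)
  x[50:60] <- 0.1 * sin(pi * (0:10) / 10)^2
  x <- x + rnorm(200, sd = 0.003)
  ev <- detect_transients(x, onset_thr = 0.07, offset_thr = 0.05)
  expect_equal(nrow(ev), 1L)
  expect_gt(ev$peak_amplitude, 0.07)
})
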