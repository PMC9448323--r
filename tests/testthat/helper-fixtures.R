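# Shared fixtures and independent oracles, all built in code.

# Straight 20-nucleus lattice: ranks spaced `spacing` um along x, sides
# offset +/- `offset` in y, optional z profile per rank.
lattice_posture <- function(spacing = 10, offset = 2, z = rep(0, 10),
                            frame = 0L) {
  ids <- seam_cell_ids()
  pos <- matrix(0, 20, 3, dimnames = list(ids, NULL))
  pos[, 1] <- rep(seq(0, by = spacing, length.out = 10), 2)
  pos[, 2] <- rep(c(offset, -offset), each = 10)
  pos[, 3] <- rep(z, 2)
  posture_state(pos, frame = frame)
}

# Random smooth-ish posture for invariance tests.
random_posture <- function(seed) {
  set.seed(seed)
  z <- 3 * sin(pi * (0:9) / 9) * runif(1, 0.2, 1) + cumsum(rnorm(10, sd = 0.3))
  st <- lattice_posture(z = z)
  pos <- st$positions + matrix(rnorm(60, sd = 0.4), ncol = 3)
  posture_state(pos)
}

rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

rigid_transform <- function(state, ax = 0.3, ay = -0.5, az = 0.9,
                            shift = c(5, -3, 2)) {
  R <- rotation_matrix(ax, ay, az)
  pos <- state$positions %*% t(R) + matrix(shift, nrow(state$positions), 3,
                                           byrow = TRUE)
  rownames(pos) <- rownames(state$positions)
  posture_state(pos, frame = state$frame)
}

mirror_posture <- function(state) {
  ids <- seam_cell_ids()
  pos <- state$positions
  swapped <- pos
  swapped[1:10, ] <- pos[11:20, ]
  swapped[11:20, ] <- pos[1:10, ]
  rownames(swapped) <- ids
  posture_state(swapped, frame = state$frame)
}

# All complete assignments of an n x m cost matrix (n <= m), by exhaustive
# enumeration; returns sorted total costs.
enumerate_assignment_costs <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  cols <- unique(lapply(perms(seq_len(m)), function(p) p[seq_len(n)]))
  sort(vapply(cols, function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1L)))
}

# Annotated corpora carry measurement noise; perturb simulated truth the
# way detections are jittered before estimating covariances.
jitter_states <- function(states, sd, seed) {
  set.seed(seed)
  posture_sequence(lapply(states, function(s) {
    p <- s$positions + matrix(rnorm(length(s$positions), sd = sd), ncol = 3)
    posture_state(p, frame = s$frame, time_s = s$time_s)
  }), frame_rate = attr(states, "frame_rate"))
}

# Short flipping-phase simulation plus corrupted detections.
flipping_scenario <- function(seed, n_frames = 18) {
  cfg <- sim_config(seed = seed, phase_schedule = data.frame(
    phase = "flipping", start_mpf = 530,
    end_mpf = 530 + (n_frames + 2) / 180))
  truth <- simulate_posture_sequence(cfg)
  keep <- seq_len(min(n_frames + 1L, length(truth$states)))
  states <- truth$states[keep]
  det <- corrupt_detections(posture_sequence(states[-1L]), cfg)
  list(config = cfg, seed_state = states[[1L]],
       truth_states = posture_sequence(states[-1L]), detections = det)
}

# Covariance model shared by tracking tests (estimated once per session).
benchmark_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 1000, phase_schedule = data.frame(
        phase = "flipping", start_mpf = 530, end_mpf = 533))
      truth <- simulate_posture_sequence(cfg)
      corpus <- jitter_states(truth$states, 0.5, 123)
      cache <<- estimate_covariances(corpus, build_embryo_graph())
    }
    cache
  }
})
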