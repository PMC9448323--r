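#' Fit a side midline with a natural cubic spline
#'
#' The ten seam-cell nuclei of one body side are interpolated, in rank
#' order, by a natural cubic spline (zero second derivative at the ends)
#' through each coordinate against cumulative chord length.
#'
#' @param points 10 x 3 matrix of nucleus positions, anterior to posterior.
#' @return An object of class `side_midline`: `eval(s)` evaluates the curve
#'   at arc fractions `s` in `[0, 1]` (chord-length parameterization);
#'   `knots` gives the arc fractions of the input points.
#' @export
fit_side_midline <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, all(is.finite(points)))
  seglen <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                            points[-nrow(points), , drop = FALSE])^2))
  if (any(seglen == 0)) stop("coincident consecutive points")
  tknots <- c(0, cumsum(seglen))
  total <- tknots[length(tknots)]
  tknots <- tknots / total
  fx <- stats::splinefun(tknots, points[, 1L], method = "natural")
  fy <- stats::splinefun(tknots, points[, 2L], method = "natural")
  fz <- stats::splinefun(tknots, points[, 3L], method = "natural")
  structure(list(
    eval = function(s) cbind(x = fx(s), y = fy(s), z = fz(s)),
    knots = tknots, length_um = total
  ), class = "side_midline")
}

side_points <- function(state, side) {
  tab <- seam_cell_table()
  ids <- tab$id[tab$side == side][order(tab$rank[tab$side == side])]
  state$positions[ids, , drop = FALSE]
}

dv_bend_angle <- function(v1, v2, v3) {
  n2 <- sqrt(sum(v2 * v2))
  if (n2 == 0) stop("degenerate lateral axis (|v2| = 0)")
  cr <- function(a, b) c(a[2L] * b[3L] - a[3L] * b[2L],
                         a[3L] * b[1L] - a[1L] * b[3L],
                         a[1L] * b[2L] - a[2L] * b[1L])
  c12 <- cr(v1, v2)
  c23 <- cr(v2, v3)
  atan2(sum(cr(c12, c23) * (v2 / n2)), sum(c12 * c23))
}

#' Dorsoventral bend-angle profile of a posture
#'
#' Both body sides are fit with natural cubic splines ([fit_side_midline()]).
#' For each of the nine gaps between adjacent seam cells on a side, the
#' spline midpoint of the gap (`mSide`) and the midpoint of the same rank
#' gap on the opposite side (`mOpp`) define the local frame, and the signed
#' dorsoventral bend is the dihedral angle
#' `atan2(((v1 x v2) x (v2 x v3)) . v2/|v2|, (v1 x v2) . (v2 x v3))`
#' where `v1` runs from `mSide` to the anterior cell of the gap, `v2` from
#' `mOpp` to `mSide`, and `v3` from `mSide` to the posterior cell. The 18
#' angles are ordered left side anterior to posterior, then right side.
#'
#' @param state A complete 20-nucleus [posture_state()].
#' @return Numeric vector of 18 signed angles (radians) with names
#'   `L1..L9`, `R1..R9`; attribute `frame`.
#' @export
compute_bend_profile <- function(state) {
  if (!is_full_embryo_state(state))
    stop("compute_bend_profile requires a full 20-nucleus state")
  pl <- side_points(state, "L")
  pr <- side_points(state, "R")
  sl <- fit_side_midline(pl)
  sr <- fit_side_midline(pr)
  gapmid <- function(sp) {
    s <- (sp$knots[-10L] + sp$knots[-1L]) / 2
    sp$eval(s)
  }
  mL <- gapmid(sl)
  mR <- gapmid(sr)
  ang <- numeric(18L)
  for (g in 1:9) {
    # left side: v2 runs from the right midpoint to the left midpoint
    ang[g] <- dv_bend_angle(pl[g, ] - mL[g, ], mL[g, ] - mR[g, ],
                            pl[g + 1L, ] - mL[g, ])
    # right side: mirror construction
    ang[9L + g] <- dv_bend_angle(pr[g, ] - mR[g, ], mR[g, ] - mL[g, ],
                                 pr[g + 1L, ] - mR[g, ])
  }
  names(ang) <- c(paste0("L", 1:9), paste0("R", 1:9))
  attr(ang, "frame") <- state$frame
  ang
}

#' Bend-angle profiles for a posture sequence
#'
#' @param states A `posture_sequence` (or list of states).
#' @return Numeric matrix, one row per frame, 18 columns.
#' @export
compute_bend_profiles <- function(states) {
  out <- t(vapply(states, compute_bend_profile, numeric(18L)))
  rownames(out) <- NULL
  out
}

#' Fit eigen-embryos (posture PCA)
#'
#' Mean-centered principal component analysis of 18-dimensional bend-angle
#' profiles. Angles share units, so no rescaling is applied. Each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive; dorsal/ventral semantics are applied afterwards via
#' [assign_dorsal_sign()].
#'
#' @param profiles Matrix of bend profiles (rows = frames, 18 columns).
#' @return An object of class `eigen_basis`: `mean_profile`, `components`
#'   (18 x 18 orthonormal, columns ordered by variance), `explained_variance`
#'   (fractions summing to 1), `eigenvalues`, `dv_sign`.
#' @export
fit_eigen_embryos <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != 18L) stop("profiles must have 18 columns")
  if (nrow(profiles) < 19L)
    stop("need more profiles (>= 19) than bend-angle dimensions")
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  comp <- pc$rotation
  for (k in seq_len(ncol(comp))) {
    imax <- which.max(abs(comp[, k]))
    if (comp[imax, k] < 0) comp[, k] <- -comp[, k]
  }
  ev <- pc$sdev^2
  structure(list(mean_profile = pc$center, components = comp,
                 explained_variance = ev / sum(ev), eigenvalues = ev,
                 dv_sign = 1),
            class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("<eigen_basis> top-4 variance: %s (cum %.1f%%), dv_sign %+d\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance[1:4]),
                    collapse = " "),
              100 * sum(x$explained_variance[1:4]), x$dv_sign))
  invisible(x)
}

#' Project bend profiles onto an eigen-embryo basis
#'
#' @param profile An 18-vector or a matrix of profiles (rows = frames).
#' @param basis An `eigen_basis`.
#' @return Amplitude vector (or matrix), one value per component; the
#'   basis `dv_sign` is applied to PC1.
#' @export
project_amplitudes <- function(profile, basis) {
  x <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1L)
  a <- sweep(x, 2L, basis$mean_profile) %*% basis$components
  a[, 1L] <- basis$dv_sign * a[, 1L]
  colnames(a) <- paste0("pc", seq_len(ncol(a)))
  if (is.matrix(profile)) a else drop(a)
}

#' Reconstruct a bend profile from leading amplitudes
#'
#' @param amplitudes Numeric vector of the leading k amplitudes (k <= 18).
#' @param basis An `eigen_basis`.
#' @return List with `profile` (18-vector) and `residual_variance` (sum of
#'   the trailing eigenvalues, the expected mean squared reconstruction
#'   error over the fitting set).
#' @export
reconstruct_profile <- function(amplitudes, basis) {
  k <- length(amplitudes)
  if (k > 18L) stop("at most 18 amplitudes")
  a <- amplitudes
  if (k >= 1L) a[1L] <- basis$dv_sign * a[1L]
  prof <- basis$mean_profile
  if (k >= 1L)
    prof <- prof + drop(basis$components[, seq_len(k), drop = FALSE] %*% a)
  resid <- if (k < 18L) sum(basis$eigenvalues[(k + 1L):18L]) else 0
  list(profile = prof, residual_variance = resid)
}

#' Fix the dorsal sign convention from late-stage postures
#'
#' Late-stage embryos exhibit a dorsal coiling bias; the PC1 sign is chosen
#' so that the late-window amplitude distribution skews positive (dorsal).
#'
#' @param pc1_trace PC1 amplitude series.
#' @param late_window Integer indices of the late analysis window.
#' @return `+1` or `-1`. A symmetric (zero-mean) window returns `+1` with a
#'   warning.
#' @export
assign_dorsal_sign <- function(pc1_trace, late_window) {
  if (!length(late_window)) stop("empty late window")
  m <- mean(pc1_trace[late_window])
  if (m == 0) {
    warning("late-window PC1 distribution is symmetric; keeping +1")
    return(1)
  }
  sign(m)
}

#' Detect dorsoventral flips from a PC1 amplitude trace
#'
#' Coil states are defined by `|PC1| >= coil_threshold` times the 95th
#' percentile of `|PC1|` over the trace, signed. A flip is the interval
#' from the last exit of one coil state to the first entry of the opposite
#' state. Flips longer than `max_duration_s` are discarded as non-flips.
#'
#' @param pc1_trace PC1 amplitude series.
#' @param frame_rate Frames per second (default 3).
#' @param coil_threshold Fraction of the 95th percentile of `|PC1|` that
#'   counts as fully coiled (default 0.5).
#' @param max_duration_s Discard transitions longer than this (default 30).
#' @return Data frame of flips: `start_frame`, `end_frame` (1-based),
#'   `direction` (`"dorsal->ventral"` / `"ventral->dorsal"` under the
#'   convention that positive PC1 is dorsal), `duration_s`.
#' @export
detect_flips <- function(pc1_trace, frame_rate = 3, coil_threshold = 0.5,
                         max_duration_s = 30) {
  if (length(pc1_trace) <= 2L) stop("trace too short")
  thr <- coil_threshold * stats::quantile(abs(pc1_trace), 0.95, names = FALSE)
  st <- integer(length(pc1_trace))
  st[pc1_trace >= thr] <- 1L
  st[pc1_trace <= -thr] <- -1L
  coil_idx <- which(st != 0L)
  out <- data.frame(start_frame = integer(), end_frame = integer(),
                    direction = character(), duration_s = numeric(),
                    stringsAsFactors = FALSE)
  if (!length(coil_idx)) return(out)
  prev_idx <- coil_idx[1L]
  for (i in coil_idx[-1L]) {
    if (st[i] != st[prev_idx]) {
      dur <- (i - prev_idx) / frame_rate
      if (dur <= max_duration_s) {
        dirn <- if (st[prev_idx] > 0L) "dorsal->ventral" else "ventral->dorsal"
        out <- rbind(out, data.frame(start_frame = prev_idx, end_frame = i,
                                     direction = dirn, duration_s = dur,
                                     stringsAsFactors = FALSE))
      }
    }
    prev_idx <- i
  }
  out
}

#' Classify a flip into a posture-space motif
#'
#' The motif is the principal component (PC2 or PC3) with the larger mean
#' absolute amplitude over the transition, suffixed with the sign of that
#' mean; ties go to PC2. The motif indicates where along the body the flip
#' initiates (e.g. PC2- flips start in the tail).
#'
#' @param flip One row of [detect_flips()] output (or a list with
#'   `start_frame`, `end_frame`).
#' @param pc2_trace,pc3_trace Amplitude series aligned with the PC1 trace
#'   the flip was detected on.
#' @return One of `"PC2+"`, `"PC2-"`, `"PC3+"`, `"PC3-"`.
#' @export
classify_flip_motif <- function(flip, pc2_trace, pc3_trace) {
  idx <- flip$start_frame:flip$end_frame
  m2 <- mean(pc2_trace[idx])
  m3 <- mean(pc3_trace[idx])
  if (abs(m2) >= abs(m3)) paste0("PC2", if (m2 >= 0) "+" else "-")
  else paste0("PC3", if (m3 >= 0) "+" else "-")
}
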