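# Internal helpers.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# Every stochastic routine in the package draws from its own seeded stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trailing moving mean with span k (mean of the up-to-k samples ending at t).
trailing_mean <- function(x, k) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  from <- pmax(seq_len(n) - k, 0L)
  (cs[seq_len(n) + 1L] - cs[from + 1L]) / (seq_len(n) - from)
}

# Separable Gaussian smoothing of a matrix with symmetric (reflective)
# boundary padding.
gaussian_blur <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  reflect_idx <- function(n) {
    idx <- c(r:1, seq_len(n), n:(n - r + 1L))
    idx[idx < 1L] <- 1L; idx[idx > n] <- n
    idx
  }
  pass <- function(m) {  # filter along rows (dimension 1)
    n <- nrow(m)
    p <- m[reflect_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(k)) out <- out + k[o] * p[(o - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(pass(t(pass(img))))
}
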