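#' Simulate bend profiles from a low-dimensional latent basis
#'
#' Generates 18-dimensional bend-angle profiles as `A s + e`: `A` has four
#' orthonormal columns (smooth sinusoidal posture modes), the latent
#' amplitudes `s` are independent Gaussians, and `e` is isotropic Gaussian
#' noise. The latent variances are calibrated so that the *population*
#' principal components explain the requested shares of total variance:
#' with the default shares (60, 16, 8 and 4 percent, plus a 12 percent
#' isotropic noise floor) the top four population components explain 88
#' percent, matching the low-dimensional structure of real embryo
#' postures. Because isotropic noise contributes variance along the latent
#' directions too, the calibration solves
#' `sigma^2 = noise_share * total / (18 - 4)` and
#' `lambda_k = share_k * total - sigma^2`, so that the population
#' eigenvalues `(lambda_k + sigma^2, ..., sigma^2, ...)` have exactly the
#' requested shares.
#'
#' @param n Number of profiles.
#' @param ev_shares Population explained-variance shares of the latent
#'   components (fractions; default `c(0.60, 0.16, 0.08, 0.04)`).
#' @param noise_share Population variance share of the isotropic noise
#'   floor (default 0.12).
#' @param total_var Total population variance (default 1; scale only).
#' @param seed RNG seed.
#' @return List: `profiles` (n x 18), `basis` (18 x 4 orthonormal),
#'   `latent_var`, `noise_var`, `population_ev` (the 18 population
#'   explained-variance fractions).
#' @export
simulate_bend_profiles <- function(n, ev_shares = c(0.60, 0.16, 0.08, 0.04),
                                   noise_share = 0.12, total_var = 1,
                                   seed = 1L) {
  d <- 18L
  k <- length(ev_shares)
  stopifnot(abs(sum(ev_shares) + noise_share - 1) < 1e-9)
  # population eigenvalues are lambda_k + sigma^2 on the latent directions
  # and sigma^2 on the remaining d - k; matching the requested shares gives
  # (d - k) * sigma^2 = noise_share * total and lambda_k = share_k*total - sigma^2
  sigma2 <- noise_share * total_var / (d - k)
  lambda <- ev_shares * total_var - sigma2
  if (any(lambda <= 0)) stop("noise share too large for the latent shares")
  u <- seq(0.5, d - 0.5) / d
  A <- cbind(sin(pi * u), sin(2 * pi * u), cos(2 * pi * u), sin(3 * pi * u))
  A <- qr.Q(qr(A))
  pop_eig <- c(lambda + sigma2, rep(sigma2, d - k))
  with_seed(seed, {
    S <- matrix(stats::rnorm(n * k), n, k) %*% diag(sqrt(lambda))
    E <- matrix(stats::rnorm(n * d, sd = sqrt(sigma2)), n, d)
    X <- S %*% t(A) + E
    colnames(X) <- c(paste0("L", 1:9), paste0("R", 1:9))
    list(profiles = X, basis = A, latent_var = lambda, noise_var = sigma2,
         population_ev = pop_eig / sum(pop_eig))
  })
}
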