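# Latent AR(1) utilities.
#
# The latent series of a centre observed at integer month indices t_1 <
# ... < t_T is the stationary Gaussian AR(1) process with marginal sd
# `sigma` and lag-one correlation `phi`; observations separated by a gap of
# d months have correlation phi^d. The Markov structure makes the precision
# matrix tridiagonal even with gaps, and gives the log-determinant in
# closed form.

# Dense tridiagonal precision matrix of the latent values at `times`.
ar1_precision <- function(times, sigma, phi) {
  T <- length(times)
  if (sigma <= 0) stop("'sigma' must be positive")
  if (T == 1L) return(matrix(1 / sigma^2, 1, 1))
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  rho <- phi^diff(times)              # per-step correlations
  a <- 1 - rho^2
  d <- numeric(T)
  d[1] <- 1
  d[2:T] <- 1 / a
  d[1:(T - 1)] <- d[1:(T - 1)] + rho^2 / a
  off <- -rho / a
  Q <- diag(d, T)
  Q[cbind(1:(T - 1), 2:T)] <- off
  Q[cbind(2:T, 1:(T - 1))] <- off
  Q / sigma^2
}

# log determinant of ar1_precision(times, sigma, phi), closed form.
ar1_logdet_precision <- function(times, sigma, phi) {
  T <- length(times)
  if (T == 1L) return(-2 * log(sigma))
  rho <- phi^diff(times)
  -2 * T * log(sigma) - sum(log1p(-rho^2))
}

# Simulate one stationary path at `times` via the Markov factorisation.
simulate_ar1 <- function(times, sigma, phi) {
  T <- length(times)
  u <- numeric(T)
  if (T == 0L) return(u)
  u[1] <- rnorm(1, 0, sigma)
  if (T > 1L) {
    rho <- phi^diff(times)
    for (k in 2:T) u[k] <- rnorm(1, rho[k - 1] * u[k - 1],
                                 sigma * sqrt(1 - rho[k - 1]^2))
  }
  u
}
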