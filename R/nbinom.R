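#' NB2 log probability mass function
#'
#' Log density of the negative binomial distribution in the quadratic
#' ("NB2") parameterisation with mean `mu` and dispersion `theta`, i.e.
#' variance `mu * (1 + mu / theta)`. Evaluated directly from the
#' log-gamma representation, which is numerically stable for large counts
#' and large means, and tends to the Poisson log pmf as `theta` grows.
#'
#' @param y non-negative integer count(s).
#' @param mu positive mean(s).
#' @param theta positive dispersion(s); larger is closer to Poisson.
#' @return log pmf value(s), recycled to common length.
#' @examples
#' nb2_logpmf(3, 2, 1e8)  # ~ dpois(3, 2, log = TRUE)
#' @export
nb2_logpmf <- function(y, mu, theta) {
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(theta <= 0)) stop("'theta' must be positive")
  if (any(y < 0) || any(y != round(y))) stop("'y' must be non-negative integer")
  n <- max(length(y), length(mu), length(theta))
  y <- rep_len(y, n); mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * (log(theta) - log(mu + theta)) +
    y * (log(mu) - log(mu + theta))
}

# log pmf of the zero-inflated NB2: structural zero with probability p,
# otherwise NB2(mu, theta). Stable via log-sum-exp at y = 0.
zinb_logpmf <- function(y, mu, theta, p) {
  n <- max(length(y), length(mu), length(theta), length(p))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  theta <- rep_len(theta, n); p <- rep_len(p, n)
  ll <- log1p(-p) + nb2_logpmf(y, mu, theta)
  z <- y == 0
  if (any(z)) {
    a <- log(p[z])
    b <- ll[z]
    m <- pmax(a, b)
    # p = 0 gives a = -Inf; the NB branch alone remains
    ll[z] <- ifelse(is.finite(m), m + log(exp(a - m) + exp(b - m)), b)
  }
  ll
}

#' Marginal mean of a zero-inflated count
#'
#' Expected count under the zero-inflation mixture: `(1 - p) * mu`, where
#' `p` is the structural-zero probability and `mu` the conditional
#' (non-structural-zero) mean.
#'
#' @param p structural-zero probability in \[0, 1\].
#' @param mu positive conditional mean.
#' @return the unconditional expected count.
#' @export
zinb_unconditional_mean <- function(p, mu) {
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  (1 - p) * mu
}
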