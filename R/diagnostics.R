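# Simulation-based residual diagnostics.
#
# Randomized-quantile residuals: each observation's residual is its
# (randomised) empirical quantile within replicate responses simulated
# from the fitted generative model. Under correct specification the
# residuals are uniform on (0, 1); summary checks are a KS test against
# uniformity, a dispersion ratio (observed vs simulated response
# variability) and a count of observations outside the simulation
# envelope.

#' Simulate replicate responses from a fitted model
#'
#' Draws `n_sim` response vectors from the fitted generative model at the
#' dataset's covariates: Gaussian with the fitted mean and log-linear
#' variance for the ratio models, and the full zero-inflation, dispersion
#' and latent AR(1) structure for the disease-count model.
#'
#' @param fit a `denomcast_fit`.
#' @param data the dataset the fit was made on (covariate source).
#' @param n_sim number of replicate response vectors.
#' @param seed RNG seed.
#' @return numeric matrix, `nrow(data)` x `n_sim`.
#' @export
simulate_from_fit <- function(fit, data, n_sim = 250L, seed = 1L) {
  stopifnot(inherits(fit, "denomcast_fit"))
  if (!fit$converged)
    warning("simulating from a fit that did not converge", call. = FALSE)
  set.seed(seed)
  n <- nrow(data)
  out <- matrix(NA_real_, n, n_sim)
  if (n_sim == 0L) return(out)
  if (inherits(fit$params, "gaussian_disp_params")) {
    mu <- linear_predictor(fit$params$mean, data)
    sdv <- sqrt(exp(linear_predictor(fit$params$logvar, data)))
    for (s in seq_len(n_sim)) out[, s] <- rnorm(n, mu, sdv)
  } else {
    p <- fit$params
    ord <- order(data$centre_id, data$month_index)
    if (any(ord != seq_len(n)))
      stop("data must be ordered by centre and month")
    eta0 <- linear_predictor(p$conditional, data)
    theta <- exp(linear_predictor(p$dispersion, data))
    pz <- if (is.null(p$zi)) rep(0, n)
          else plogis(linear_predictor(p$zi, data))
    groups <- split(seq_len(n), data$centre_id)
    for (s in seq_len(n_sim)) {
      u <- numeric(n)
      if (p$sigma_ar > 0)
        for (ix in groups)
          u[ix] <- simulate_ar1(data$month_index[ix], p$sigma_ar, p$phi)
      mu <- exp(pmin(eta0 + u, 30))
      y <- rnbinom(n, mu = mu, size = theta)
      y[rbinom(n, 1L, pz) == 1L] <- 0L
      out[, s] <- y
    }
  }
  out
}

#' Randomized-quantile residual diagnostics
#'
#' Computes the randomised empirical quantile of each observed response
#' within its simulated distribution, the Kolmogorov-Smirnov test of the
#' residuals against U(0, 1), the dispersion ratio (observed variance of
#' centred responses over the mean simulated variance) and the number of
#' observations beyond the simulation envelope at the 0.5% tails.
#'
#' @param fit a `denomcast_fit`.
#' @param data the dataset with the response column.
#' @param n_sim simulation replicates (default 250).
#' @param seed RNG seed (also used for tie randomisation).
#' @param response response column; defaults to `"n_cases"` for count fits
#'   and `"r"` for ratio fits.
#' @return object of class `residual_diagnostics` with elements
#'   `residuals`, `ks_statistic`, `ks_p_value`, `dispersion_ratio`,
#'   `n_outliers`, `n_sim`.
#' @export
quantile_residuals <- function(fit, data, n_sim = 250L, seed = 1L,
                               response = NULL) {
  if (is.null(response))
    response <- if (inherits(fit$params, "gaussian_disp_params")) "r"
                else "n_cases"
  y <- data[[response]]
  if (is.null(y)) stop("missing response column: ", response)
  sims <- simulate_from_fit(fit, data, n_sim, seed)
  n <- length(y)
  set.seed(seed + 1L)
  resid <- numeric(n)
  for (i in seq_len(n)) {
    s <- sims[i, ]
    p_lt <- mean(s < y[i])
    p_eq <- mean(s == y[i])
    resid[i] <- p_lt + runif(1) * p_eq
  }
  # keep residuals in the open interval for the KS test
  resid <- pmin(pmax(resid, 0.5 / n_sim), 1 - 0.5 / n_sim)
  ks <- suppressWarnings(ks.test(resid, "punif"))
  centred <- y - rowMeans(sims)
  disp_ratio <- var(centred) / mean(apply(sims, 1, var))
  lo <- apply(sims, 1, quantile, 0.005, names = FALSE)
  hi <- apply(sims, 1, quantile, 0.995, names = FALSE)
  structure(list(residuals = resid,
                 ks_statistic = unname(ks$statistic),
                 ks_p_value = ks$p.value,
                 dispersion_ratio = disp_ratio,
                 n_outliers = sum(y < lo | y > hi),
                 n_sim = n_sim),
            class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat("Simulation-based residual diagnostics\n")
  cat(sprintf("  KS vs uniform: D = %.3f, p = %.3f\n",
              x$ks_statistic, x$ks_p_value))
  cat(sprintf("  dispersion ratio = %.2f, envelope outliers = %d (n_sim = %d)\n",
              x$dispersion_ratio, x$n_outliers, x$n_sim))
  invisible(x)
}
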