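# Prediction chains on unmatched data.
#
# Relationship 2 predicts the patient-occupancy ratio (and hence patients)
# from occupancy rows; relationship 3 predicts the ratio (and hence
# occupancy) from EHR rows; chaining relationship 2 into relationship 1
# predicts disease incidence with respect to occupancy where no EHR exists.
# Out-of-sample predictions from the disease-count model set the latent
# AR(1) contribution to its stationary mean (zero on the log scale),
# because unmatched rows may come from centres absent from training.

mean_coef <- function(fit) {
  if (!inherits(fit, "denomcast_fit") ||
      !inherits(fit$params, "gaussian_disp_params"))
    stop("a Gaussian ratio model fit is required")
  fit$params$mean
}

mean_block_vcov <- function(fit) {
  nm <- paste0("mean.", names(fit$params$mean))
  if (is.null(fit$vcov)) return(NULL)
  fit$vcov[nm, nm, drop = FALSE]
}

new_prediction <- function(rows, target, point, lower, upper, method,
                           flags = "") {
  data.frame(centre_id = rows$centre_id, year_month = rows$year_month,
             target = target, point = point, lower95 = lower,
             upper95 = upper, method = method, flags = flags,
             stringsAsFactors = FALSE)
}

#' Predict the patient-occupancy ratio
#'
#' Point prediction is the mean-model linear predictor of a fitted ratio
#' model evaluated at the rows' covariates; the interval reflects the
#' sampling uncertainty of the coefficients (Wald/delta or parametric
#' bootstrap).
#'
#' @param fit a `denomcast_fit` from [fit_relationship2()] or
#'   [fit_relationship3()].
#' @param rows data frame carrying the fit's covariate columns.
#' @param interval `"wald_delta"`, `"parametric_bootstrap"` or `"none"`.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed seed for the bootstrap.
#' @return data frame of `PredictionResult` rows (point, lower95, upper95,
#'   method, flags).
#' @export
predict_ratio <- function(fit, rows,
                          interval = c("parametric_bootstrap", "wald_delta",
                                       "none"),
                          n_boot = 1000L, seed = 1L) {
  interval <- match.arg(interval)
  beta <- mean_coef(fit)
  X <- design_from_coef(beta, rows)
  point <- as.vector(X %*% beta)
  lower <- upper <- rep(NA_real_, length(point))
  if (interval == "wald_delta") {
    V <- mean_block_vcov(fit)
    if (is.null(V)) stop("fit carries no covariance matrix")
    se <- sqrt(pmax(rowSums((X %*% V) * X), 0))
    lower <- point - qnorm(0.975) * se
    upper <- point + qnorm(0.975) * se
  } else if (interval == "parametric_bootstrap") {
    draws <- bootstrap_coef_draws(mean_block_vcov(fit), beta, n_boot, seed)
    sim <- X %*% t(draws)                     # n x n_boot
    qs <- apply(sim, 1, quantile, c(0.025, 0.975), names = FALSE)
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  # intervals always bracket the point estimate
  lower <- pmin(lower, point); upper <- pmax(upper, point)
  new_prediction(rows, "ratio", point, lower, upper, interval)
}

# Draw coefficient vectors from the Gaussian approximation N(beta, V).
bootstrap_coef_draws <- function(V, beta, n_boot, seed) {
  if (n_boot < 100L)
    warning("n_boot < 100 gives unstable percentile intervals",
            call. = FALSE)
  if (is.null(V)) stop("fit carries no covariance matrix")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  k <- length(beta)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  Z <- matrix(rnorm(n_boot * k), n_boot, k)
  out <- sweep(Z %*% t(L), 2, beta, "+")
  colnames(out) <- names(beta)
  out
}

#' Predict patient counts from occupancy rows (relationship 2 chain)
#'
#' `n_pat = r_hat * n_occ`; interval endpoints scale with `n_occ`.
#' Rows with a non-positive predicted ratio are flagged and returned
#' without a prediction rather than silently fixed.
#'
#' @inheritParams predict_ratio
#' @param fit2 ratio-given-occupancy fit ([fit_relationship2()]).
#' @return prediction data frame with target `"n_pat"`.
#' @export
predict_patients <- function(fit2, rows, interval = "parametric_bootstrap",
                             n_boot = 1000L, seed = 1L) {
  pr <- predict_ratio(fit2, rows, interval, n_boot, seed)
  flags <- ifelse(pr$point <= 0, "nonpositive ratio", "")
  if (any(rows$n_occ == 0)) {
    warning("rows with zero occupancy predict zero patients", call. = FALSE)
    flags[rows$n_occ == 0] <- paste0(flags[rows$n_occ == 0], ";zero occupancy")
  }
  point <- ifelse(pr$point > 0, pr$point * rows$n_occ, NA_real_)
  out <- new_prediction(rows, "n_pat", point,
                        pmax(pr$lower95, 0) * rows$n_occ,
                        pr$upper95 * rows$n_occ, pr$method, flags)
  out$point[rows$n_occ == 0] <- 0
  out[pr$point <= 0, c("lower95", "upper95")] <- NA_real_
  out
}

#' Predict occupancy from EHR rows (relationship 3 chain)
#'
#' `n_occ = n_pat / r_hat`; rows with non-positive predicted ratio are
#' flagged. Intervals propagate the ratio interval through the reciprocal
#' (delta method on the Wald scale, direct recomputation under the
#' bootstrap).
#'
#' @inheritParams predict_ratio
#' @param fit3 ratio-given-patients fit ([fit_relationship3()]).
#' @return prediction data frame with target `"n_occ"`.
#' @export
predict_occupancy <- function(fit3, rows, interval = "parametric_bootstrap",
                              n_boot = 1000L, seed = 1L) {
  interval <- match.arg(interval,
                        c("parametric_bootstrap", "wald_delta", "none"))
  beta <- mean_coef(fit3)
  X <- design_from_coef(beta, rows)
  rhat <- as.vector(X %*% beta)
  ok <- rhat > 0
  point <- ifelse(ok, rows$n_pat / rhat, NA_real_)
  lower <- upper <- rep(NA_real_, length(rhat))
  if (interval == "wald_delta") {
    V <- mean_block_vcov(fit3)
    se_r <- sqrt(pmax(rowSums((X %*% V) * X), 0))
    se <- rows$n_pat * se_r / rhat^2
    lower <- point - qnorm(0.975) * se
    upper <- point + qnorm(0.975) * se
  } else if (interval == "parametric_bootstrap") {
    draws <- bootstrap_coef_draws(mean_block_vcov(fit3), beta, n_boot, seed)
    rsim <- X %*% t(draws)
    rsim[rsim <= 0] <- NA
    osim <- sweep(1 / rsim, 1, rows$n_pat, "*")
    qs <- apply(osim, 1, quantile, c(0.025, 0.975), names = FALSE,
                na.rm = TRUE)
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  lower <- pmin(lower, point); upper <- pmax(upper, point)
  lower[!ok] <- upper[!ok] <- NA_real_
  new_prediction(rows, "n_occ", point, lower, upper, interval,
                 flags = ifelse(ok, "", "nonpositive ratio"))
}

# Expected cases from the disease-count model at given covariates, latent
# at its stationary mean: (1 - p) * mu.
expected_cases_at <- function(case_params, rows) {
  mu <- exp(linear_predictor(case_params$conditional, rows))
  p <- if (is.null(case_params$zi)) rep(0, nrow(rows))
       else plogis(linear_predictor(case_params$zi, rows))
  zinb_unconditional_mean(p, mu)
}

#' Predict disease incidence with respect to occupancy (chained)
#'
#' For occupancy rows without an EHR: first the ratio model given occupancy
#' predicts the patient count; then the disease-count model, evaluated at
#' the same centre type and demographics (patient demographics are assumed
#' equal to occupancy demographics) and the predicted patient count,
#' yields the expected cases `(1 - p) * mu` with the latent process at its
#' stationary mean. Incidence is expected cases over occupancy.
#'
#' @param fit2 ratio-given-occupancy fit.
#' @param fit1 disease-count fit ([fit_relationship1()]).
#' @param rows occupancy rows with demographics (`pct_adult_occ`,
#'   `pct_male_occ`), `n_occ` and `centre_type`.
#' @param interval `"parametric_bootstrap"` (default) or `"none"`;
#'   the chain has no closed-form Wald interval.
#' @param n_boot,seed bootstrap settings.
#' @return prediction data frame with target `"incidence_wrt_occ"` plus a
#'   column `expected_cases`.
#' @export
predict_incidence_wrt_occupancy <- function(fit1, fit2, rows,
                                            interval = c("parametric_bootstrap",
                                                         "none"),
                                            n_boot = 1000L, seed = 1L) {
  interval <- match.arg(interval)
  if (!inherits(fit1$params, "zinb_ar1_params"))
    stop("'fit1' must be a disease-count model fit")
  chain_point <- incidence_chain(fit1$params, mean_coef(fit2), rows)
  lower <- upper <- rep(NA_real_, nrow(rows))
  if (interval == "parametric_bootstrap") {
    d2 <- bootstrap_coef_draws(mean_block_vcov(fit2), mean_coef(fit2),
                               n_boot, seed)
    p1 <- fit1_param_draws(fit1, n_boot, seed + 1L)
    sims <- matrix(NA_real_, nrow(rows), n_boot)
    for (b in seq_len(n_boot))
      sims[, b] <- incidence_chain(p1[[b]], d2[b, ], rows)$incidence
    qs <- apply(sims, 1, quantile, c(0.025, 0.975), names = FALSE,
                na.rm = TRUE)
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  point <- chain_point$incidence
  lower <- pmin(lower, point); upper <- pmax(upper, point)
  out <- new_prediction(rows, "incidence_wrt_occ", point, lower, upper,
                        interval,
                        flags = ifelse(chain_point$ok, "",
                                       "nonpositive ratio"))
  out$expected_cases <- chain_point$expected_cases
  out
}

# One pass through the chain at given parameter values.
incidence_chain <- function(case_params, ratio_beta, rows) {
  X <- design_from_coef(ratio_beta, rows)
  rhat <- as.vector(X %*% ratio_beta)
  ok <- rhat > 0
  npat_hat <- ifelse(ok, rhat * rows$n_occ, NA_real_)
  ehr_view <- data.frame(pct_adult_pat = rows$pct_adult_occ,
                         pct_male_pat = rows$pct_male_occ,
                         n_pat = npat_hat,
                         centre_type = rows$centre_type,
                         stringsAsFactors = FALSE)
  ec <- rep(NA_real_, nrow(rows))
  if (any(ok)) ec[ok] <- expected_cases_at(case_params,
                                           ehr_view[ok, , drop = FALSE])
  inc <- ifelse(rows$n_occ > 0, ec / rows$n_occ, NA_real_)
  list(incidence = inc, expected_cases = ec, n_pat = npat_hat, ok = ok)
}

# Draw zinb_ar1_params from the Gaussian approximation of a relationship-1
# fit (latent block parameters are irrelevant for stationary-mean
# prediction and are kept fixed).
fit1_param_draws <- function(fit1, n_boot, seed) {
  est <- fit1$coefficients
  V <- fit1$vcov
  if (is.null(V)) stop("fit1 carries no covariance matrix")
  draws <- bootstrap_coef_draws(V, est, n_boot, seed)
  cn <- names(fit1$params$conditional)
  zn <- names(fit1$params$zi)
  dn <- names(fit1$params$dispersion)
  lapply(seq_len(n_boot), function(b) {
    v <- draws[b, ]
    zinb_ar1_params(
      setNames(v[paste0("cond.", cn)], cn),
      if (is.null(zn)) NULL else setNames(v[paste0("zi.", zn)], zn),
      setNames(v[paste0("disp.", dn)], dn),
      fit1$params$sigma_ar, fit1$params$phi)
  })
}

#' Parametric-bootstrap intervals for any prediction chain
#'
#' Convenience wrapper: draws coefficient vectors from the fitted
#' estimators' Gaussian approximations, recomputes the requested chain for
#' each draw and takes the 2.5/97.5 percentiles. Reproducible under `seed`.
#'
#' @param fits named list with the fits the chain needs: `fit2` and/or
#'   `fit3` and/or `fit1`.
#' @param rows input rows for the chain.
#' @param chain `"ratio_occ"`, `"ratio_pat"`, `"patients"`, `"occupancy"`
#'   or `"incidence"`.
#' @param n_boot number of bootstrap draws (warning below 100).
#' @param seed RNG seed.
#' @return prediction data frame for the chain with bootstrap intervals.
#' @export
bootstrap_intervals <- function(fits, rows,
                                chain = c("patients", "occupancy",
                                          "incidence", "ratio_occ",
                                          "ratio_pat"),
                                n_boot = 1000L, seed = 1L) {
  chain <- match.arg(chain)
  switch(chain,
    ratio_occ = predict_ratio(fits$fit2, rows, "parametric_bootstrap",
                              n_boot, seed),
    ratio_pat = predict_ratio(fits$fit3, rows, "parametric_bootstrap",
                              n_boot, seed),
    patients = predict_patients(fits$fit2, rows, "parametric_bootstrap",
                                n_boot, seed),
    occupancy = predict_occupancy(fits$fit3, rows, "parametric_bootstrap",
                                  n_boot, seed),
    incidence = predict_incidence_wrt_occupancy(fits$fit1, fits$fit2, rows,
                                                "parametric_bootstrap",
                                                n_boot, seed))
}

#' Observed-vs-predicted scatter plot
#'
#' Basic diagnostic scatter of observed values against predictions, with
#' the identity line; points are coloured by centre type when available.
#'
#' @param observed numeric vector of observations.
#' @param predictions prediction data frame (uses its `point` column).
#' @param rows optional data with `centre_type` for colouring.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plot_observed_vs_predicted <- function(observed, predictions, rows = NULL,
                                       ...) {
  col <- if (!is.null(rows) && "centre_type" %in% names(rows))
    ifelse(rows$centre_type == "REG", "blue", "black") else "black"
  graphics::plot(observed, predictions$point, col = col,
                 xlab = "observed", ylab = "predicted", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}
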