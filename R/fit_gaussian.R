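#' Fit a Gaussian ratio model with a log-linear variance submodel
#'
#' Joint maximum likelihood for the patient-occupancy ratio
#' `r = n_pat / n_occ`: the mean is a linear predictor in the supplied
#' covariates and the variance is `exp(z' gamma)` with its own covariate
#' list. With an intercept-only variance model the mean coefficients
#' coincide with ordinary least squares and the variance estimate is the
#' (ML, divisor n) residual variance.
#'
#' @param data data frame carrying the response and covariate columns.
#' @param mean_covariates,variance_covariates covariate names (see
#'   [build_design()] conventions: `pct_*` per 10 points, `n_*` per 10
#'   persons, `centre_type` as REG indicator). Use `"1"` or `character(0)`
#'   for an intercept-only part.
#' @param response name of the response column (default `"r"`).
#' @return a `denomcast_fit` with coefficients prefixed `mean.` and
#'   `logvar.`.
#' @seealso [fit_relationship2()], [fit_relationship3()]
#' @export
fit_gaussian_ratio <- function(data, mean_covariates,
                               variance_covariates = character(0),
                               response = "r") {
  if (!response %in% names(data)) stop("missing response column: ", response)
  y <- data[[response]]
  if (anyNA(y)) stop("response contains missing values")
  X <- build_design(data, mean_covariates)
  Z <- build_design(data, variance_covariates)
  n <- length(y)
  kb <- ncol(X); kg <- ncol(Z)
  if (n <= kb + kg) stop("fewer observations than parameters")

  negll <- function(par) {
    beta <- par[seq_len(kb)]
    gam <- par[kb + seq_len(kg)]
    lv <- as.vector(Z %*% gam)
    if (any(lv > 30) || any(lv < -30)) return(1e10)
    resid2 <- (y - as.vector(X %*% beta))^2
    0.5 * sum(log(2 * pi) + lv + resid2 * exp(-lv))
  }

  ols <- lm.fit(X, y)
  b0 <- ols$coefficients
  b0[!is.finite(b0)] <- 0
  s2 <- mean(ols$residuals^2)
  noiseless <- s2 < 1e-12
  g0 <- c(log(max(s2, 1e-10)), rep(0, kg - 1L))
  start <- c(b0, g0)
  opt <- nlminb(start, negll,
                control = list(rel.tol = 1e-10, iter.max = 500))
  par_hat <- opt$par
  converged <- opt$convergence == 0
  if (!converged && !noiseless) {
    # nlminb's curvature test can report "false convergence" at a genuine
    # optimum; accept if a quasi-Newton polish cannot improve the value
    polish <- optim(par_hat, negll, method = "BFGS",
                    control = list(maxit = 200, reltol = 1e-12))
    if (polish$value <= opt$objective + 1e-8) {
      converged <- opt$objective - polish$value < 1e-6
      if (polish$value < opt$objective) {
        par_hat <- polish$par
        opt$objective <- polish$value
      }
    }
  }
  nm <- c(paste0("mean.", colnames(X)), paste0("logvar.", colnames(Z)))
  vc <- NULL
  if (!noiseless) {
    H <- tryCatch(optimHess(par_hat, negll), error = function(e) NULL)
    vc <- invert_hessian(H, nm)
  }
  params <- gaussian_disp_params(
    mean = setNames(par_hat[seq_len(kb)], colnames(X)),
    logvar = setNames(par_hat[kb + seq_len(kg)], colnames(Z)))
  fit <- new_fit_result(
    relationship = "gaussian_ratio",
    params = params,
    coefficients = setNames(par_hat, nm),
    vcov = vc,
    loglik = -opt$objective,
    n_obs = n,
    converged = converged || noiseless,
    optimizer = list(method = "nlminb", iterations = opt$iterations,
                     message = opt$message),
    covariates = list(mean = mean_covariates,
                      variance = variance_covariates),
    boundary = noiseless,
    data_id = dataset_id(data))
  if (kg == 1L)
    fit$dispersion_estimate <- unname(exp(par_hat[kb + 1L]))
  fit
}

#' Fit the ratio model given occupancy data (relationship 2)
#'
#' Gaussian model for `r = n_pat / n_occ` on the matched data with
#' occupancy-side covariates (adult and male occupancy percentages, centre
#' type and total occupancy) and a constant variance.
#'
#' @param data matched centre-month data frame.
#' @param ... passed to [fit_gaussian_ratio()].
#' @return a `denomcast_fit`.
#' @export
fit_relationship2 <- function(data, ...) {
  f <- fit_gaussian_ratio(data,
    mean_covariates = c("pct_adult_occ", "pct_male_occ", "centre_type",
                        "n_occ"),
    variance_covariates = character(0), ...)
  f$relationship <- "ratio_given_occupancy"
  f
}

#' Fit the ratio model given patient data (relationship 3)
#'
#' Gaussian model for `r = n_pat / n_occ` on the matched data with
#' patient-side covariates (adult and male patient percentages and centre
#' type) and a log-linear variance depending on the patient count.
#'
#' @inheritParams fit_relationship2
#' @return a `denomcast_fit`.
#' @export
fit_relationship3 <- function(data, ...) {
  f <- fit_gaussian_ratio(data,
    mean_covariates = c("pct_adult_pat", "pct_male_pat", "centre_type"),
    variance_covariates = "n_pat", ...)
  f$relationship <- "ratio_given_patients"
  f
}
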