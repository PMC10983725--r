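# FitResult container shared by all fitted models.

# Invert a numerically differentiated Hessian; falls back to an
# eigenvalue-clipped pseudo-inverse when the Hessian is not positive
# definite (flat or boundary directions get very wide intervals instead of
# no covariance at all).
invert_hessian <- function(H, names = NULL) {
  if (is.null(H) || any(!is.finite(H))) return(NULL)
  H <- (H + t(H)) / 2
  vc <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(vc)) {
    ev <- eigen(H, symmetric = TRUE)
    tol <- max(abs(ev$values)) * 1e-10
    inv_vals <- ifelse(ev$values > tol, 1 / ev$values, 1 / tol)
    vc <- ev$vectors %*% (inv_vals * t(ev$vectors))
    warning("Hessian not positive definite; pseudo-inverse covariance ",
            "(intervals in flat directions are very wide)", call. = FALSE)
  }
  if (!is.null(names)) dimnames(vc) <- list(names, names)
  vc
}

new_fit_result <- function(relationship, params, coefficients, vcov, loglik,
                           n_obs, converged, optimizer, covariates,
                           boundary = FALSE, data_id = NULL) {
  k <- length(coefficients)
  structure(list(
    relationship = relationship,
    params = params,
    coefficients = coefficients,
    vcov = vcov,
    loglik = loglik,
    AIC = 2 * k - 2 * loglik,
    df = k,
    n_obs = n_obs,
    converged = converged,
    boundary = boundary,
    optimizer = optimizer,
    covariates = covariates,
    data_id = data_id
  ), class = "denomcast_fit")
}

#' @export
print.denomcast_fit <- function(x, ...) {
  cat(sprintf("denomcast fit: %s (n = %d)\n", x$relationship, x$n_obs))
  cat(sprintf("  log-likelihood %.3f, AIC %.1f, %d free parameters\n",
              x$loglik, x$AIC, x$df))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  if (x$boundary) cat("  note: latent sd at boundary (sigma_ar ~ 0)\n")
  print(wald_ci(x))
  invisible(x)
}

#' @export
logLik.denomcast_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' Wald confidence intervals for a fitted model
#'
#' Intervals `estimate +/- z * se` on the estimation (link) scale, with
#' standard errors from the numerically differentiated Hessian at the
#' optimum, optionally exponentiated (incidence-rate-ratio / odds scale).
#'
#' @param fit a `denomcast_fit` object.
#' @param level confidence level (default 0.95).
#' @param transform `"none"` for link-scale intervals, `"exp"` to
#'   exponentiate estimate and bounds.
#' @return data frame with term, estimate, se, lower and upper columns.
#' @export
wald_ci <- function(fit, level = 0.95, transform = c("none", "exp")) {
  stopifnot(inherits(fit, "denomcast_fit"))
  transform <- match.arg(transform)
  est <- fit$coefficients
  se <- if (is.null(fit$vcov)) rep(NA_real_, length(est))
        else sqrt(pmax(diag(fit$vcov), 0))
  if (!is.null(fit$vcov) &&
      (any(!is.finite(fit$vcov)) ||
       inherits(try(solve(fit$vcov), silent = TRUE), "try-error")))
    warning("covariance is singular or ill-conditioned; intervals are wide",
            call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  lo <- est - z * se
  hi <- est + z * se
  out <- data.frame(term = names(est), estimate = est, se = se,
                    lower = lo, upper = hi, row.names = NULL)
  if (transform == "exp") {
    out$estimate <- exp(out$estimate)
    out$lower <- exp(out$lower)
    out$upper <- exp(out$upper)
    out$se <- NULL
  }
  out
}

#' Rank fitted models by AIC
#'
#' Used for covariate selection between candidate specifications fitted on
#' the same dataset: returns the models ordered by increasing Akaike
#' information criterion.
#'
#' @param ... `denomcast_fit` objects (optionally named).
#' @return data frame with model, k, loglik, AIC and delta_AIC columns,
#'   ascending in AIC.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "denomcast_fit")) fits <- fits[[1]]
  if (!length(fits)) stop("no fits supplied")
  for (f in fits) stopifnot(inherits(f, "denomcast_fit"))
  ns <- vapply(fits, function(f) f$n_obs, 0)
  ids <- vapply(fits, function(f)
    if (is.null(f$data_id)) NA_character_ else f$data_id, "")
  if (length(unique(ns)) > 1L ||
      (all(!is.na(ids)) && length(unique(ids)) > 1L))
    stop("models were not fitted on the same dataset")
  lab <- names(fits)
  if (is.null(lab) || any(lab == ""))
    lab <- vapply(seq_along(fits), function(i) {
      if (!is.null(names(fits)) && nzchar(names(fits)[i])) names(fits)[i]
      else paste0(fits[[i]]$relationship, " #", i)
    }, "")
  out <- data.frame(
    model = lab,
    k = vapply(fits, function(f) f$df, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    AIC = vapply(fits, function(f) f$AIC, 0)
  )
  out <- out[order(out$AIC), , drop = FALSE]
  out$delta_AIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}

# Serialise / restore a fit (schema-versioned JSON).
#' Write or read a fitted model as JSON
#'
#' @param fit a `denomcast_fit` object.
#' @param path file path.
#' @return `read_fit_json` returns the restored `denomcast_fit`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "denomcast_fit"))
  obj <- list(
    schema = "denomcast_fit/1",
    relationship = fit$relationship,
    coefficients = as.list(fit$coefficients),
    vcov = fit$vcov,
    loglik = fit$loglik, AIC = fit$AIC, df = fit$df, n_obs = fit$n_obs,
    converged = fit$converged, boundary = fit$boundary,
    optimizer = fit$optimizer, covariates = fit$covariates,
    params = unclass_params(fit$params),
    param_class = class(fit$params)[1]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

unclass_params <- function(p) {
  if (inherits(p, "zinb_ar1_params"))
    list(conditional = as.list(p$conditional),
         zi = if (is.null(p$zi)) NULL else as.list(p$zi),
         dispersion = as.list(p$dispersion),
         sigma_ar = p$sigma_ar, phi = p$phi)
  else if (inherits(p, "gaussian_disp_params"))
    list(mean = as.list(p$mean), logvar = as.list(p$logvar))
  else unclass(p)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "denomcast_fit/1"))
    stop("unrecognised fit schema: ", obj$schema)
  params <- if (identical(obj$param_class, "zinb_ar1_params"))
    zinb_ar1_params(unlist(obj$params$conditional),
                    if (length(obj$params$zi)) unlist(obj$params$zi) else NULL,
                    unlist(obj$params$dispersion),
                    obj$params$sigma_ar, obj$params$phi)
  else
    gaussian_disp_params(unlist(obj$params$mean), unlist(obj$params$logvar))
  vc <- obj$vcov
  if (!is.null(vc)) vc <- as.matrix(vc)
  coefs <- unlist(obj$coefficients)
  if (!is.null(vc)) dimnames(vc) <- list(names(coefs), names(coefs))
  new_fit_result(obj$relationship, params, coefs, vc, obj$loglik,
                 obj$n_obs, obj$converged, obj$optimizer, obj$covariates,
                 boundary = isTRUE(obj$boundary))
}
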