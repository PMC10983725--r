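# Shared helpers: hand-built fits with known coefficients (for prediction
# arithmetic) and a finite-difference gradient.

ratio_fit_from <- function(params, vcov_diag = NULL) {
  coefs <- c(setNames(params$mean, paste0("mean.", names(params$mean))),
             setNames(params$logvar, paste0("logvar.", names(params$logvar))))
  vc <- NULL
  if (!is.null(vcov_diag)) {
    vc <- diag(vcov_diag, length(coefs))
    dimnames(vc) <- list(names(coefs), names(coefs))
  }
  denomcast:::new_fit_result("gaussian_ratio", params, coefs, vc,
                             loglik = 0, n_obs = 1L, converged = TRUE,
                             optimizer = list(), covariates = list())
}

case_fit_from <- function(params, vcov_diag = 0) {
  coefs <- c(setNames(params$conditional,
                      paste0("cond.", names(params$conditional))),
             if (!is.null(params$zi))
               setNames(params$zi, paste0("zi.", names(params$zi))),
             setNames(params$dispersion,
                      paste0("disp.", names(params$dispersion))),
             log_sigma_ar = log(max(params$sigma_ar, 1e-8)),
             atanh_phi = atanh(params$phi))
  vc <- diag(vcov_diag, length(coefs))
  dimnames(vc) <- list(names(coefs), names(coefs))
  denomcast:::new_fit_result("zinb_ar1", params, coefs, vc, loglik = 0,
                             n_obs = 1L, converged = TRUE,
                             optimizer = list(), covariates = list())
}

fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

table1_coefs <- list(
  ratio_occ = default_ratio_occ_params(),
  ratio_pat = default_ratio_pat_params(),
  cases = default_case_params()
)
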