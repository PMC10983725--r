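# Gaussian ratio models against closed-form oracles.

test_that("constant-variance ML equals the normal-equations solution", {
  d <- simulate_ratio_panel(default_ratio_occ_params(), seed = 1)
  f <- fit_relationship2(d)
  X <- cbind(1, d$pct_adult_occ / 10, d$pct_male_occ / 10,
             as.numeric(d$centre_type == "REG"), d$n_occ / 10)
  beta_ols <- solve(crossprod(X), crossprod(X, d$r))
  expect_equal(unname(f$params$mean), as.vector(beta_ols), tolerance = 1e-6)
  # ML variance = residual sum of squares / n
  expect_equal(f$dispersion_estimate,
               mean((d$r - X %*% beta_ols)^2), tolerance = 1e-6)
  expect_equal(f$AIC, 2 * f$df - 2 * f$loglik)
})

test_that("noiseless data is recovered exactly and flagged at the boundary", {
  d <- simulate_ratio_panel(default_ratio_occ_params(), seed = 2)
  beta <- c(0.1, 0.07, -0.02, 0.3, 0.001)
  d$r <- beta[1] + beta[2] * d$pct_adult_occ / 10 +
    beta[3] * d$pct_male_occ / 10 +
    beta[4] * (d$centre_type == "REG") + beta[5] * d$n_occ / 10
  f <- fit_relationship2(d)
  expect_equal(unname(f$params$mean), beta, tolerance = 1e-6)
  expect_true(f$boundary)
  expect_null(f$vcov)
})

test_that("log-linear variance model is estimated jointly", {
  set.seed(9)
  n <- 4000
  d <- data.frame(x = rnorm(n))
  gamma <- c(-2, 0.5)
  d$r <- 1 + 0.3 * d$x + rnorm(n, 0, sqrt(exp(gamma[1] + gamma[2] * d$x)))
  f <- fit_gaussian_ratio(d, mean_covariates = "x",
                          variance_covariates = "x")
  expect_equal(unname(f$params$mean), c(1, 0.3), tolerance = 0.05)
  expect_equal(unname(f$params$logvar), gamma, tolerance = 0.1)
})

test_that("degenerate inputs raise informative errors", {
  d <- simulate_ratio_panel(n = 4L, seed = 3)
  expect_error(fit_relationship2(d), "fewer observations")
  d2 <- simulate_ratio_panel(n = 30L, seed = 3)
  d2$pct_adult_occ <- NULL
  expect_error(fit_relationship2(d2), "pct_adult_occ")
})

test_that("REC/REG relabelling gives an equivalent fit", {
  d <- simulate_ratio_panel(default_ratio_occ_params(), seed = 4)
  f1 <- fit_relationship2(d)
  d2 <- d
  d2$centre_type <- ifelse(d$centre_type == "REG", "REC", "REG")
  f2 <- fit_relationship2(d2)
  # indicator flip: intercept absorbs the REG effect, slope flips sign
  expect_equal(f2$params$mean[["centre_typeREG"]],
               -f1$params$mean[["centre_typeREG"]], tolerance = 1e-5)
  expect_equal(f2$params$mean[["(Intercept)"]],
               f1$params$mean[["(Intercept)"]] +
                 f1$params$mean[["centre_typeREG"]], tolerance = 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
})

test_that("wald_ci gives standard-normal quantile intervals", {
  p <- gaussian_disp_params(mean = c("(Intercept)" = 0),
                            logvar = c("(Intercept)" = 0))
  f <- ratio_fit_from(p, vcov_diag = c(1, 0))
  # the zero-se row makes the covariance singular: warning expected
  expect_warning(ci <- wald_ci(f), "singular")
  expect_equal(ci$lower[1], -qnorm(0.975), tolerance = 1e-10)
  expect_equal(ci$upper[1], qnorm(0.975), tolerance = 1e-10)
  # exponentiated zero-se interval collapses to (1, 1)
  ci_exp <- suppressWarnings(wald_ci(f, transform = "exp"))
  expect_equal(unlist(ci_exp[2, c("lower", "upper")]), c(1, 1),
               ignore_attr = TRUE)
})

test_that("compare_models ranks by AIC and computes deltas", {
  p <- gaussian_disp_params(mean = c("(Intercept)" = 0, a = 1, b = 2),
                            logvar = c("(Intercept)" = 0))
  mk <- function(ll) denomcast:::new_fit_result(
    "toy", p, c(x = 1, y = 2, z = 3), NULL, ll, 50L, TRUE, list(), list(),
    data_id = "same")
  tab <- compare_models(m1 = mk(-10), m2 = mk(-12))
  expect_equal(tab$AIC, c(26, 30))
  expect_equal(tab$model, c("m1", "m2"))
  expect_equal(tab$delta_AIC, c(0, 4))
  expect_equal(compare_models(mk(-10), mk(-10))$delta_AIC, c(0, 0))
  bad <- denomcast:::new_fit_result("toy", p, c(x = 1), NULL, -1, 49L, TRUE,
                                    list(), list(), data_id = "other")
  expect_error(compare_models(mk(-10), bad), "same dataset")
})

test_that("adding a null covariate rarely improves AIC on large data", {
  set.seed(31)
  wins <- 0L
  for (r in 1:10) {
    d <- simulate_ratio_panel(default_ratio_occ_params(), n = 800L,
                              seed = 500 + r)
    d$noise <- rnorm(nrow(d))
    f0 <- fit_relationship2(d)
    f1 <- fit_gaussian_ratio(d,
      mean_covariates = c("pct_adult_occ", "pct_male_occ", "centre_type",
                          "n_occ", "noise"))
    tab <- compare_models(small = f0, big = f1)
    if (tab$model[1] == "small" || tab$delta_AIC[2] <= 2) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("fit JSON round-trips", {
  d <- simulate_ratio_panel(default_ratio_occ_params(), seed = 8)
  f <- fit_relationship2(d)
  path <- tempfile(fileext = ".json")
  write_fit_json(f, path)
  g <- read_fit_json(path)
  expect_equal(g$coefficients, f$coefficients, tolerance = 1e-12)
  expect_equal(g$vcov, f$vcov, tolerance = 1e-10)
  expect_equal(g$AIC, f$AIC)
  expect_s3_class(g$params, "gaussian_disp_params")
})
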