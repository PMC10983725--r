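# Marginal-likelihood oracle equivalences and engine agreement.

make_panel <- function(sigma, seed, n_total = 80, n_centres = 6) {
  simulate_case_panel(default_case_params(sigma_ar = sigma),
                      n_total = n_total, n_centres = n_centres, seed = seed)
}

test_that("AR(1) precision inverts the stationary covariance, with gaps", {
  for (times in list(0:5, c(0L, 1L, 4L, 5L, 9L), 3L)) {
    sigma <- 0.7; phi <- 0.85
    S <- sigma^2 * phi^abs(outer(times, times, "-"))
    Q <- denomcast:::ar1_precision(times, sigma, phi)
    expect_equal(Q %*% S, diag(length(times)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(denomcast:::ar1_logdet_precision(times, sigma, phi),
                 determinant(Q)$modulus[1], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("sigma_ar = 0 reduces exactly to the closed-form ZINB sum", {
  d <- make_panel(0.4, seed = 2)
  p0 <- default_case_params(sigma_ar = 0)
  mu <- exp(log(3.55) + log(1.03) * d$pct_adult_pat / 10 +
              log(1.12) * d$pct_male_pat / 10 + log(1.03) * d$n_pat / 10)
  th <- ifelse(d$centre_type == "REG", 3.11 * 7.05, 3.11)
  pz <- plogis(log(0.44) + log(0.93) * d$n_pat / 10)
  manual <- sum(denomcast:::zinb_logpmf(d$n_cases, mu, th, pz))
  expect_lt(abs(as.numeric(marginal_loglik_zinb_ar1(p0, d)) - manual), 1e-8)
})

test_that("single-observation latent case matches Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  d <- make_panel(0.4, seed = 2)
  gh <- pracma::gaussHermite(80)
  pars <- default_case_params(sigma_ar = 0.7)
  for (i in c(1L, which(d$n_cases == 0)[1], 17L)) {
    di <- d[i, , drop = FALSE]
    mu <- exp(log(3.55) + log(1.03) * di$pct_adult_pat / 10 +
                log(1.12) * di$pct_male_pat / 10 + log(1.03) * di$n_pat / 10)
    th <- ifelse(di$centre_type == "REG", 3.11 * 7.05, 3.11)
    pz <- plogis(log(0.44) + log(0.93) * di$n_pat / 10)
    oracle <- log(sum(gh$w / sqrt(pi) *
      exp(denomcast:::zinb_logpmf(di$n_cases, mu * exp(sqrt(2) * 0.7 * gh$x),
                                  th, pz))))
    for (engine in c("cpp", "r", "filter"))
      expect_lt(abs(as.numeric(
        marginal_loglik_zinb_ar1(pars, di, engine = engine)) - oracle), 1e-4)
  }
})

test_that("duplicating every observation doubles the loglik when sigma = 0", {
  d <- make_panel(0.3, seed = 4, n_total = 40, n_centres = 4)
  p0 <- default_case_params(sigma_ar = 0)
  d2 <- rbind(d, within(d, centre_id <- paste0(centre_id, "bis")))
  expect_equal(2 * as.numeric(marginal_loglik_zinb_ar1(p0, d)),
               as.numeric(marginal_loglik_zinb_ar1(p0, d2)),
               tolerance = 1e-10)
})

test_that("compiled and plain-R Laplace engines agree at random points", {
  d <- make_panel(0.5, seed = 3)
  set.seed(11)
  for (i in 1:4) {
    pp <- default_case_params()
    pp$conditional <- pp$conditional + rnorm(4, 0, 0.15)
    pp$zi <- pp$zi + rnorm(2, 0, 0.2)
    pp$sigma_ar <- runif(1, 0.1, 0.9)
    pp$phi <- runif(1, -0.5, 0.95)
    lc <- as.numeric(marginal_loglik_zinb_ar1(pp, d, engine = "cpp"))
    lr <- as.numeric(marginal_loglik_zinb_ar1(pp, d, engine = "r"))
    expect_lt(abs(lc - lr), 1e-6)
  }
})

test_that("grid filter is grid-converged and bounds the Laplace value", {
  d <- make_panel(0.5, seed = 6)
  pars <- default_case_params(sigma_ar = 0.5)
  prep <- denomcast:::prep_zinb_data(
    d, c("pct_adult_pat", "pct_male_pat", "n_pat"), "n_pat", "centre_type")
  l81 <- denomcast:::zinb_ar1_loglik_prep(pars, prep, engine = "filter",
                                          grid_size = 81L)
  l241 <- denomcast:::zinb_ar1_loglik_prep(pars, prep, engine = "filter",
                                           grid_size = 241L, grid_width = 6)
  expect_lt(abs(as.numeric(l81) - as.numeric(l241)), 1e-6)
})

test_that("the Laplace objective is smooth (Richardson-consistent gradient)", {
  d <- make_panel(0.5, seed = 8, n_total = 40, n_centres = 4)
  prep <- denomcast:::prep_zinb_data(
    d, c("pct_adult_pat", "pct_male_pat", "n_pat"), "n_pat", "centre_type")
  f <- function(v) {
    p <- zinb_ar1_params(
      setNames(v[1:4], colnames(prep$X)),
      setNames(v[5:6], colnames(prep$Z)),
      setNames(v[7:8], colnames(prep$D)), exp(v[9]), tanh(v[10]))
    as.numeric(denomcast:::zinb_ar1_loglik_prep(p, prep))
  }
  set.seed(21)
  for (rep in 1:2) {
    x <- c(log(3.55), log(1.03), log(1.12), log(1.03), log(0.44), log(0.93),
           log(3.11), log(7.05), log(0.5), atanh(0.9)) + rnorm(10, 0, 0.05)
    g1 <- fd_gradient(f, x, h = 1e-4)
    g2 <- fd_gradient(f, x, h = 5e-5)
    expect_lt(max(abs(g1 - g2)), 1e-3 * (1 + max(abs(g1))))
  }
})
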