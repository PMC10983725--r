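# Prediction chains and their printed-coefficient arithmetic.

occ_row <- function(type = "REC", adult = 80, male = 60, n_occ = 200) {
  data.frame(centre_id = "X", year_month = "2019-06", centre_type = type,
             pct_adult_occ = adult, pct_male_occ = male, n_occ = n_occ,
             stringsAsFactors = FALSE)
}

test_that("ratio prediction reproduces the published worked example", {
  f2 <- ratio_fit_from(default_ratio_occ_params())
  pr <- predict_ratio(f2, occ_row(), interval = "none")
  expect_equal(pr$point, -0.01 + 0.08 * 8 - 0.01 * 6 + 0 * 20,
               tolerance = 1e-12)
  expect_equal(pr$point, 0.57)
  # REG vs REC difference equals the REG coefficient
  prg <- predict_ratio(f2, occ_row(type = "REG"), interval = "none")
  expect_equal(prg$point - pr$point, 0.32, tolerance = 1e-12)
  # intercept-only coefficients give a constant prediction
  fc <- ratio_fit_from(gaussian_disp_params(
    mean = c("(Intercept)" = 0.4), logvar = c("(Intercept)" = -3)))
  expect_equal(predict_ratio(fc, occ_row(n_occ = 999),
                             interval = "none")$point, 0.4)
  expect_error(predict_ratio(f2, occ_row()[, -4], interval = "none"),
               "pct_adult_occ")
})

test_that("patient prediction scales the ratio by occupancy", {
  f2 <- ratio_fit_from(default_ratio_occ_params())
  pp <- predict_patients(f2, occ_row(), interval = "none")
  expect_equal(pp$point, 0.57 * 200)
  expect_equal(pp$point, 114)
  one <- ratio_fit_from(gaussian_disp_params(
    mean = c("(Intercept)" = 1), logvar = c("(Intercept)" = -3)))
  expect_equal(predict_patients(one, occ_row(n_occ = 50),
                                interval = "none")$point, 50)
  expect_warning(
    z <- predict_patients(one, occ_row(n_occ = 0), interval = "none"),
    "zero occupancy")
  expect_equal(z$point, 0)
  neg <- ratio_fit_from(gaussian_disp_params(
    mean = c("(Intercept)" = -0.2), logvar = c("(Intercept)" = -3)))
  flagged <- predict_patients(neg, occ_row(), interval = "none")
  expect_true(is.na(flagged$point))
  expect_match(flagged$flags, "nonpositive")
})

test_that("occupancy prediction reproduces the published worked example", {
  f3 <- ratio_fit_from(default_ratio_pat_params())
  row <- data.frame(centre_id = "Y", year_month = "2019-06",
                    centre_type = "REG", pct_adult_pat = 80,
                    pct_male_pat = 60, n_pat = 130)
  po <- predict_occupancy(f3, row, interval = "none")
  rhat <- 0.37 - 0.02 * 8 + 0.04 * 6 + 0.20
  expect_equal(rhat, 0.65)
  expect_equal(po$point, 130 / 0.65)
  expect_equal(po$point, 200)
  # REG-vs-REC ratio difference is the printed 0.20
  rowc <- row; rowc$centre_type <- "REC"
  expect_equal(predict_ratio(f3, row, interval = "none")$point -
                 predict_ratio(f3, rowc, interval = "none")$point, 0.20,
               tolerance = 1e-12)
  half <- ratio_fit_from(gaussian_disp_params(
    mean = c("(Intercept)" = 0.5), logvar = c("(Intercept)" = -3)))
  row$n_pat <- 100
  expect_equal(predict_occupancy(half, row, interval = "none")$point, 200)
})

test_that("round trip: patients then occupancy at the same ratio is exact", {
  f2 <- ratio_fit_from(default_ratio_occ_params())
  rows <- do.call(rbind, lapply(c(120, 350, 801), function(n)
    occ_row(n_occ = n)))
  rhat <- predict_ratio(f2, rows, interval = "none")$point
  npat <- predict_patients(f2, rows, interval = "none")$point
  expect_equal(npat / rhat, rows$n_occ, tolerance = 1e-12)
})

test_that("chained incidence matches the printed-coefficient arithmetic", {
  f1 <- case_fit_from(default_case_params())
  f2 <- ratio_fit_from(default_ratio_occ_params())
  pi <- predict_incidence_wrt_occupancy(f1, f2, occ_row(),
                                        interval = "none")
  # direct arithmetic on the published coefficients
  npat_hat <- 0.57 * 200
  mu <- 3.55 * 1.03^8 * 1.12^6 * 1.03^(npat_hat / 10)
  podds <- 0.44 * 0.93^(npat_hat / 10)
  p <- podds / (1 + podds)
  expect_equal(pi$expected_cases, (1 - p) * mu, tolerance = 1e-12)
  expect_equal(pi$point, (1 - p) * mu / 200, tolerance = 1e-12)
  expect_lt(abs(pi$point - 0.05), 0.01)
  # degenerate zero-inflation regime: incidence collapses to zero
  allzi <- default_case_params()
  allzi$zi["(Intercept)"] <- 40
  expect_lt(predict_incidence_wrt_occupancy(case_fit_from(allzi), f2,
                                            occ_row(),
                                            interval = "none")$point, 1e-10)
  # monotonicity in occupancy (positive printed n_pat effects)
  rows <- rbind(occ_row(n_occ = 100), occ_row(n_occ = 200),
                occ_row(n_occ = 400))
  ec <- predict_incidence_wrt_occupancy(f1, f2, rows,
                                        interval = "none")$expected_cases
  expect_true(all(diff(ec) > 0))
})

test_that("incidence w.r.t. occupancy is below incidence w.r.t. patients", {
  st <- generate_study(generator_config(seed = 17, n_centres = 40))
  m <- st$truth[st$truth$n_pat <= st$truth$n_occ & st$truth$n_pat > 0, ]
  inc_pat <- mean(m$n_cases / m$n_pat)
  inc_occ <- mean(m$n_cases / m$n_occ)
  expect_lt(inc_occ, inc_pat)
})

test_that("bootstrap intervals are seeded, centred and scale linearly", {
  p <- default_ratio_occ_params()
  f0 <- ratio_fit_from(p, vcov_diag = rep(0, 6))
  rows <- occ_row()
  b0 <- predict_ratio(f0, rows, n_boot = 300, seed = 5)
  expect_equal(b0$lower95, b0$point)
  expect_equal(b0$upper95, b0$point)
  v <- c(1e-4, 1e-5, 1e-5, 1e-5, 1e-8, 0)
  f1 <- ratio_fit_from(p, vcov_diag = v)
  f4 <- ratio_fit_from(p, vcov_diag = 4 * v)
  b1 <- predict_ratio(f1, rows, n_boot = 500, seed = 5)
  b4 <- predict_ratio(f4, rows, n_boot = 500, seed = 5)
  expect_equal(b4$upper95 - b4$lower95, 2 * (b1$upper95 - b1$lower95),
               tolerance = 1e-9)
  expect_identical(b1, predict_ratio(f1, rows, n_boot = 500, seed = 5))
  expect_true(b1$lower95 <= b1$point && b1$point <= b1$upper95)
  expect_warning(predict_ratio(f1, rows, n_boot = 50, seed = 5), "n_boot")
  # wrapper dispatches chains
  bw <- bootstrap_intervals(list(fit2 = f1), rows, "patients",
                            n_boot = 300, seed = 2)
  expect_equal(bw$target, "n_pat")
})
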