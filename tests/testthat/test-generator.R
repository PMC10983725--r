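# Synthetic panel generator: determinism, construction invariants and
# calibration against the documented marginal structure.

test_that("config validation names the offending field", {
  expect_error(generator_config(n_centres = -1), "n_centres")
  expect_error(generator_config(months_range = c(0, 10)), "months_range")
  expect_error(generator_config(matched_fraction = 0.5,
                                ehr_only_fraction = 0.5,
                                occ_only_fraction = 0.5),
               "matched_fraction")
  expect_error(generator_config(duplicate_report_rate = 2),
               "duplicate_report_rate")
  expect_error(generator_config(occupancy_mean = -5), "occupancy_mean")
})

test_that("centre roster is typed, windowed and reproducible", {
  cfg <- generator_config(seed = 1)
  c1 <- generate_centres(cfg)
  c2 <- generate_centres(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 21L)
  expect_true(all(c1$centre_type %in% c("REC", "REG")))
  expect_true(all(c1$n_months >= 2 & c1$n_months <= 45))
  expect_true(all(c1$start_month >= 0 &
                    c1$start_month + c1$n_months <= 45))
  expect_equal(nrow(generate_centres(generator_config(n_centres = 0))), 0L)
})

test_that("whole study generation is deterministic under the seed", {
  s1 <- generate_study(generator_config(seed = 7, n_centres = 8))
  s2 <- generate_study(generator_config(seed = 7, n_centres = 8))
  expect_identical(s1$ehr, s2$ehr)
  expect_identical(s1$occupancy, s2$occupancy)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_study(generator_config(seed = 8, n_centres = 8))
  expect_false(identical(s1$ehr, s3$ehr))
})

test_that("occupancy strata always add up and zero spread degenerates", {
  st <- generate_study(generator_config(seed = 3, n_centres = 15))
  tr <- st$truth
  expect_true(all(tr$n_male_adult + tr$n_female_adult == tr$n_adult))
  expect_true(all(tr$n_male_child + tr$n_female_child == tr$n_child))
  expect_true(all(tr$n_adult + tr$n_child == tr$n_occ))
  cfg0 <- generator_config(seed = 4, n_centres = 5, occupancy_sd = 0)
  occ0 <- generate_occupancy(generate_centres(cfg0), cfg0)
  expect_lte(diff(range(occ0$n_occ)), 2)
})

test_that("noiseless ratio model inverts exactly", {
  occ <- data.frame(centre_id = "C01", centre_type = "REC",
                    month_index = 0:9, year_month = index_to_ym(0:9),
                    n_occ = 100, pct_male_occ = 60, pct_adult_occ = 80)
  rp <- gaussian_disp_params(mean = c("(Intercept)" = 0.5),
                             logvar = c("(Intercept)" = -60))
  cfg <- generator_config(seed = 1, high_turnover_fraction = 0)
  set.seed(1)
  pat <- generate_patients(occ, rp, cfg)
  expect_true(all(pat$n_pat == 50L))
  expect_true(all(pat$r_true == 0.5))
})

test_that("ratios above one only arise from high-turnover injection", {
  cfg <- generator_config(seed = 5, n_centres = 40,
                          high_turnover_fraction = 0)
  st <- generate_study(cfg)
  expect_true(all(st$truth$n_pat <= st$truth$n_occ))
  cfg2 <- generator_config(seed = 5, n_centres = 40,
                           high_turnover_fraction = 0.3)
  st2 <- generate_study(cfg2)
  share <- mean(st2$truth$n_pat > st2$truth$n_occ)
  expect_gt(share, 0.15)
  expect_lt(share, 0.45)
})

test_that("case generation hits the Poisson limit and the degenerate ZI", {
  base <- data.frame(centre_id = sprintf("C%03d", 1:4000),
                     centre_type = "REC", month_index = 0L,
                     n_pat = 100, pct_adult_pat = 80, pct_male_pat = 60)
  pois_pars <- zinb_ar1_params(
    conditional = c("(Intercept)" = log(5)),
    zi = c("(Intercept)" = -40),
    dispersion = c("(Intercept)" = log(1e8)),
    sigma_ar = 0, phi = 0)
  set.seed(2)
  out <- generate_cases(base, pois_pars)
  expect_lt(abs(mean(out$n_cases_true) - 5), 3 * sqrt(5 / 4000))
  expect_lt(abs(var(out$n_cases_true) - 5), 0.5)
  all_zero <- zinb_ar1_params(
    conditional = c("(Intercept)" = log(5)),
    zi = c("(Intercept)" = 40),
    dispersion = c("(Intercept)" = 0), sigma_ar = 0, phi = 0)
  out0 <- generate_cases(base, all_zero)
  expect_true(all(out0$n_cases_true == 0L))
})

test_that("latent series has the configured lag-one autocorrelation", {
  set.seed(6)
  u <- denomcast:::simulate_ar1(0:100000, 0.5, 0.92)
  expect_lt(abs(acf(u, plot = FALSE, lag.max = 1)$acf[2] - 0.92), 0.02)
  expect_lt(abs(sd(u) - 0.5), 0.02)
})

test_that("censoring zeroes small counts and nothing else", {
  expect_identical(apply_censoring(c(0L, 1L, 2L, 3L, 4L)),
                   c(0L, 0L, 0L, 3L, 4L))
  x <- c(0L, 5L, 17L)
  expect_identical(apply_censoring(x, threshold = 0), x)
  expect_identical(apply_censoring(rep(0L, 5)), rep(0L, 5))
  expect_error(apply_censoring(c(-1L, 2L)), "non-negative")
  st <- generate_study(generator_config(seed = 2, n_centres = 10))
  expect_true(all(st$truth$n_cases <= st$truth$n_cases_true))
  changed <- st$truth$n_cases != st$truth$n_cases_true
  expect_true(all(st$truth$n_cases_true[changed] %in% 1:2))
})

test_that("fragmentation follows the configured fractions", {
  cfg <- generator_config(seed = 11, n_centres = 60)
  st <- generate_study(cfg)
  n <- nrow(st$truth)
  shares <- prop.table(table(st$truth$destination))
  for (nm in c("matched", "ehr_only", "occ_only")) {
    frac <- switch(nm, matched = cfg$matched_fraction,
                   ehr_only = cfg$ehr_only_fraction,
                   occ_only = cfg$occ_only_fraction)
    expect_lt(abs(shares[[nm]] - frac), 4 * sqrt(frac * (1 - frac) / n))
  }
  # matched centre-months appear in both written streams
  key_e <- paste(st$ehr$centre_id, st$ehr$year_month)
  key_o <- paste(st$occupancy$centre_id, st$occupancy$year_month)
  key_m <- with(st$truth[st$truth$destination == "matched", ],
                paste(centre_id, year_month))
  expect_true(all(key_m %in% key_e))
  expect_true(all(key_m %in% key_o))
  # no duplicates when the duplicate rate is zero
  st0 <- generate_study(generator_config(seed = 11, n_centres = 20,
                                         duplicate_report_rate = 0))
  expect_equal(anyDuplicated(paste(st0$occupancy$centre_id,
                                   st0$occupancy$year_month)), 0L)
})

test_that("defaults reproduce the documented marginal means", {
  st <- generate_study(generator_config(seed = 20, n_centres = 250))
  tr <- st$truth
  expect_gt(nrow(tr), 5000)
  expect_lt(abs(mean(tr$n_occ) - 348) / 348, 0.10)
  expect_lt(abs(mean(tr$n_pat) - 230) / 230, 0.10)
  expect_lt(abs(mean(tr$n_cases / tr$n_pat) - 0.092) / 0.092, 0.10)
})

test_that("month helpers are inverse and reject malformed input", {
  expect_equal(ym_to_index("2017-11"), 0L, ignore_attr = TRUE)
  expect_equal(index_to_ym(ym_to_index("2020-03")), "2020-03",
               ignore_attr = TRUE)
  expect_equal(index_to_ym(0:3),
               c("2017-11", "2017-12", "2018-01", "2018-02"))
  expect_error(ym_to_index("2020/03"), "unparseable")
})
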