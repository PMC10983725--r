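# Lean simulators for parameter-recovery studies.
#
# These draw covariates from the marginal distributions observed in the
# surveillance panels (patient demographics ~ N(80, 10) adult and
# N(60, 14) male percent, log-normal patient and occupancy totals, REG
# shares of the respective analysis sets) and the response directly from
# the model under study, without the generator's truncation or censoring
# steps, so that refitting the same model family is a clean recovery
# experiment.

lognormal_pars <- function(mean, sd) {
  s2 <- log1p((sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a disease-count panel from generating truth
#'
#' Builds a centre-month panel of the EHR layout (default 445 rows over 21
#' centres with enrolment windows in 2-45 months) with covariates drawn
#' from the observed marginals, then simulates case counts from the
#' zero-inflated NB2 / AR(1) model at the supplied parameters. Counts are
#' returned uncensored.
#'
#' @param case_params generating [zinb_ar1_params()].
#' @param n_total total number of centre-months (window lengths are drawn
#'   uniformly and rescaled to this total).
#' @param n_centres number of centres.
#' @param n_reg number of REG centres (default `round(5/21 * n_centres)`).
#' @param months_range enrolment-window length bounds.
#' @param npat_mean,npat_sd marginal moments of the patient count.
#' @param npat_range observed patient-count range; draws are clamped to it
#'   so the log-linear count effect is only evaluated on its support.
#' @param adult_mean,adult_sd,male_mean,male_sd demographic marginals (%).
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return data frame ready for [fit_relationship1()].
#' @export
simulate_case_panel <- function(case_params = default_case_params(),
                                n_total = 445L, n_centres = 21L,
                                n_reg = NULL,
                                months_range = c(2L, 45L),
                                npat_mean = 230, npat_sd = 202,
                                npat_range = c(5L, 934L),
                                adult_mean = 80, adult_sd = 10,
                                male_mean = 60, male_sd = 14,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_reg)) n_reg <- round(5 / 21 * n_centres)
  w <- runif(n_centres, months_range[1], months_range[2])
  len <- pmax(months_range[1],
              pmin(months_range[2], round(w * n_total / sum(w))))
  # absorb rounding drift in the longest windows
  i <- 0L
  while (sum(len) != n_total && i < 1000L) {
    j <- if (sum(len) < n_total) which.min(len) else which.max(len)
    len[j] <- len[j] + sign(n_total - sum(len))
    i <- i + 1L
  }
  type <- sample(rep(c("REG", "REC"), c(n_reg, n_centres - n_reg)))
  lp <- lognormal_pars(npat_mean, npat_sd)
  rows <- lapply(seq_len(n_centres), function(i) {
    t <- seq_len(len[i]) - 1L
    n <- length(t)
    data.frame(centre_id = sprintf("C%02d", i), centre_type = type[i],
               month_index = t,
               n_pat = pmin(npat_range[2],
                            pmax(npat_range[1],
                                 round(exp(rnorm(n, lp[1], lp[2]))))),
               pct_adult_pat = pmin(100, pmax(5, rnorm(n, adult_mean, adult_sd))),
               pct_male_pat = pmin(100, pmax(5, rnorm(n, male_mean, male_sd))),
               stringsAsFactors = FALSE)
  })
  pat <- do.call(rbind, rows)
  pat <- generate_cases(pat, case_params,
                        config = NULL)  # config unused by generate_cases
  pat$n_cases <- pat$n_cases_true
  pat
}

#' Simulate a matched ratio panel from generating truth
#'
#' Draws the covariates of the matched analysis set (default 147 rows, REG
#' share 29%) and the ratio response from the Gaussian mean/log-variance
#' model at the supplied parameters, without truncation.
#'
#' @param params generating [gaussian_disp_params()]; its coefficient names
#'   determine which covariate columns are used (occupancy-side for
#'   relationship 2, patient-side for relationship 3).
#' @param n number of matched centre-months.
#' @param reg_share probability of a REG row.
#' @param adult_mean,adult_sd,male_mean,male_sd demographic marginals (%).
#' @param nocc_mean,nocc_sd,npat_mean,npat_sd totals of the matched set.
#' @param seed RNG seed, or `NULL`.
#' @return data frame with covariates and the simulated ratio `r`.
#' @export
simulate_ratio_panel <- function(params = default_ratio_occ_params(),
                                 n = 147L, reg_share = 0.29,
                                 adult_mean = 80, adult_sd = 10,
                                 male_mean = 60, male_sd = 14,
                                 nocc_mean = 394, nocc_sd = 312,
                                 npat_mean = 212, npat_sd = 195,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lpo <- lognormal_pars(nocc_mean, nocc_sd)
  lpp <- lognormal_pars(npat_mean, npat_sd)
  ad <- pmin(100, pmax(5, rnorm(n, adult_mean, adult_sd)))
  ml <- pmin(100, pmax(5, rnorm(n, male_mean, male_sd)))
  d <- data.frame(
    centre_id = sprintf("M%03d", seq_len(n)),
    centre_type = ifelse(runif(n) < reg_share, "REG", "REC"),
    pct_adult_occ = ad, pct_male_occ = ml,
    pct_adult_pat = ad, pct_male_pat = ml,
    n_occ = pmax(5, round(exp(rnorm(n, lpo[1], lpo[2])))),
    n_pat = pmax(1, round(exp(rnorm(n, lpp[1], lpp[2])))),
    stringsAsFactors = FALSE)
  mu <- linear_predictor(params$mean, d)
  sdv <- sqrt(exp(linear_predictor(params$logvar, d)))
  d$r <- rnorm(n, mu, sdv)
  d
}
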