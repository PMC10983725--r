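# Synthetic centre-month panel generator.
#
# Emulates the structure of the two surveillance streams: an EHR monitoring
# export (patient counts, demographics and censored digestive-disease case
# counts per centre-month) and an occupancy census (sex-by-age strata
# counts, possibly with duplicate reports). All counts are generated from
# the same model families the analysis fits, so ground truth is known.

#' Month index helpers
#'
#' Calendar months are encoded as integer indices from a configurable epoch
#' (default `"2017-11"` = 0), which makes gaps in a centre's series explicit.
#'
#' @param ym character vector of ISO `"YYYY-MM"` months.
#' @param index integer month indices.
#' @param epoch ISO month mapped to index 0.
#' @return `ym_to_index` returns integer indices; `index_to_ym` ISO strings.
#' @export
ym_to_index <- function(ym, epoch = "2017-11") {
  parse1 <- function(x) {
    m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{2})$", x))[[1]]
    if (length(m) != 3) stop("unparseable year_month: '", x, "'")
    as.integer(m[2]) * 12L + as.integer(m[3]) - 1L
  }
  vapply(as.character(ym), parse1, 0L) - parse1(epoch)
}

#' @rdname ym_to_index
#' @export
index_to_ym <- function(index, epoch = "2017-11") {
  e <- ym_to_index(epoch, epoch = "0000-01")  # absolute months
  abs <- e + as.integer(index)
  sprintf("%04d-%02d", abs %/% 12L, abs %% 12L + 1L)
}

# round half away from zero (11.5 -> 12), elementwise, non-negative use
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Configuration of the synthetic panel generator
#'
#' Defaults reproduce the marginal structure of the German refugee-centre
#' surveillance setting the package targets: 21 centres (REG share 5/21),
#' enrolment windows of 2-45 months within a 45-month study horizon, mean
#' occupancy 348 (sd 287), occupancy demographics around 66% male / 77%
#' adult, patient demographics equal to occupancy demographics plus bounded
#' jitter, patient counts derived from the generating ratio model, case
#' counts from the generating disease-count model, anonymisation censoring
#' of counts below 3, and fragmentation of the scheduled centre-months into
#' matched / EHR-only / occupancy-only streams.
#'
#' @param n_centres number of centres.
#' @param reg_fraction probability that a centre is of type REG.
#' @param months_range integer pair: min/max enrolment-window length.
#' @param horizon_months length of the study period in months.
#' @param occupancy_mean,occupancy_sd marginal mean/sd of total occupancy.
#' @param occupancy_range observed occupancy range; the log-normal draw is
#'   clamped to it so the disease model is only evaluated on covariate
#'   support it was estimated for.
#' @param ratio_floor smallest regular ratio (observed minimum).
#' @param npat_max largest patient count (observed maximum); `r` is
#'   recomputed after capping.
#' @param patient_male_shift,patient_adult_shift systematic offsets between
#'   occupancy and patient demographics (percentage points), matching the
#'   observed stream marginals (66 vs 60% male, 77 vs 80% adult).
#' @param male_pct_mean,male_pct_sd,adult_pct_mean,adult_pct_sd occupancy
#'   demographic percentages (means and spreads).
#' @param ratio_params [gaussian_disp_params()] generating truth of the
#'   patient-occupancy ratio (occupancy-side covariates).
#' @param case_params [zinb_ar1_params()] generating truth of the case model.
#' @param censor_threshold counts below this are exported as 0 (default 3).
#' @param censor_all_cells if `TRUE` censoring also hits the demographic
#'   strata cells; by default only the case count is censored.
#' @param matched_fraction,ehr_only_fraction,occ_only_fraction destination
#'   probabilities of a scheduled centre-month; must sum to 1.
#' @param duplicate_report_rate share of occupancy centre-months that
#'   receive a second, noisy report.
#' @param high_turnover_fraction share of centre-months whose ratio is
#'   pushed above 1 (patients exceed occupancy), exercising the exclusion
#'   rule.
#' @param demographic_jitter half-width (percentage points) of the uniform
#'   jitter between occupancy and patient demographics.
#' @param epoch ISO month mapped to month index 0.
#' @param seed integer RNG seed.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_centres = 21L,
                             reg_fraction = 5 / 21,
                             months_range = c(2L, 45L),
                             horizon_months = 45L,
                             occupancy_mean = 348,
                             occupancy_sd = 287,
                             occupancy_range = c(32L, 1516L),
                             ratio_floor = 0.13,
                             npat_max = 934L,
                             patient_male_shift = -6,
                             patient_adult_shift = 3,
                             male_pct_mean = 66, male_pct_sd = 14,
                             adult_pct_mean = 77, adult_pct_sd = 10,
                             ratio_params = default_ratio_occ_params(),
                             case_params = default_case_params(),
                             censor_threshold = 3L,
                             censor_all_cells = FALSE,
                             matched_fraction = 0.33,
                             ehr_only_fraction = 0.58,
                             occ_only_fraction = 0.09,
                             duplicate_report_rate = 0.15,
                             high_turnover_fraction = 0.16,
                             demographic_jitter = 5,
                             epoch = "2017-11",
                             seed = 1L) {
  cfg <- list(n_centres = as.integer(n_centres), reg_fraction = reg_fraction,
              months_range = as.integer(months_range),
              horizon_months = as.integer(horizon_months),
              occupancy_mean = occupancy_mean, occupancy_sd = occupancy_sd,
              occupancy_range = as.integer(occupancy_range),
              ratio_floor = ratio_floor, npat_max = as.integer(npat_max),
              patient_male_shift = patient_male_shift,
              patient_adult_shift = patient_adult_shift,
              male_pct_mean = male_pct_mean, male_pct_sd = male_pct_sd,
              adult_pct_mean = adult_pct_mean, adult_pct_sd = adult_pct_sd,
              ratio_params = ratio_params, case_params = case_params,
              censor_threshold = as.integer(censor_threshold),
              censor_all_cells = isTRUE(censor_all_cells),
              matched_fraction = matched_fraction,
              ehr_only_fraction = ehr_only_fraction,
              occ_only_fraction = occ_only_fraction,
              duplicate_report_rate = duplicate_report_rate,
              high_turnover_fraction = high_turnover_fraction,
              demographic_jitter = demographic_jitter,
              epoch = epoch, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  err <- function(field, why) stop("invalid generator config: '", field,
                                   "' ", why, call. = FALSE)
  if (cfg$n_centres < 0) err("n_centres", "must be >= 0")
  if (cfg$reg_fraction < 0 || cfg$reg_fraction > 1)
    err("reg_fraction", "must be in [0, 1]")
  if (length(cfg$months_range) != 2L || cfg$months_range[1] < 1L ||
      cfg$months_range[2] < cfg$months_range[1])
    err("months_range", "must be an increasing pair with min >= 1")
  if (cfg$months_range[2] > cfg$horizon_months)
    err("months_range", "exceeds horizon_months")
  if (cfg$occupancy_mean <= 0) err("occupancy_mean", "must be > 0")
  if (cfg$occupancy_sd < 0) err("occupancy_sd", "must be >= 0")
  if (length(cfg$occupancy_range) != 2L ||
      cfg$occupancy_range[1] < 1L ||
      cfg$occupancy_range[2] < cfg$occupancy_range[1])
    err("occupancy_range", "must be an increasing positive pair")
  if (cfg$ratio_floor <= 0 || cfg$ratio_floor >= 1)
    err("ratio_floor", "must be in (0, 1)")
  if (cfg$npat_max < 1L) err("npat_max", "must be >= 1")
  fr <- cfg$matched_fraction + cfg$ehr_only_fraction + cfg$occ_only_fraction
  if (abs(fr - 1) > 1e-9)
    err("matched_fraction", "fractions must sum to 1")
  if (cfg$duplicate_report_rate < 0 || cfg$duplicate_report_rate > 1)
    err("duplicate_report_rate", "must be in [0, 1]")
  if (cfg$censor_threshold < 0) err("censor_threshold", "must be >= 0")
  if (!inherits(cfg$ratio_params, "gaussian_disp_params"))
    err("ratio_params", "must be a gaussian_disp_params object")
  if (!inherits(cfg$case_params, "zinb_ar1_params"))
    err("case_params", "must be a zinb_ar1_params object")
  invisible(cfg)
}

#' Generate the centre roster
#'
#' Draws `n_centres` centres, typed REG with probability `reg_fraction`,
#' each with an enrolment window of uniform length within `months_range`
#' placed uniformly within the study horizon. Reproducible under the
#' config seed.
#'
#' @param config a [generator_config()].
#' @param reseed set the RNG from `config$seed` first (default TRUE;
#'   internal callers that manage the RNG themselves pass FALSE).
#' @return data frame with centre_id, centre_type, start_month, n_months.
#' @export
generate_centres <- function(config, reseed = TRUE) {
  validate_generator_config(config)
  if (reseed) set.seed(config$seed)
  n <- config$n_centres
  if (n == 0L)
    return(data.frame(centre_id = character(0), centre_type = character(0),
                      start_month = integer(0), n_months = integer(0)))
  type <- ifelse(runif(n) < config$reg_fraction, "REG", "REC")
  len <- sample(seq(config$months_range[1], config$months_range[2]),
                n, replace = TRUE)
  start <- vapply(len, function(l)
    sample(0:(config$horizon_months - l), 1L), 0L)
  data.frame(centre_id = sprintf("C%02d", seq_len(n)),
             centre_type = type, start_month = as.integer(start),
             n_months = as.integer(len), stringsAsFactors = FALSE)
}

#' Generate occupancy strata counts per centre-month
#'
#' Total occupancy is log-normal with the configured marginal mean and sd,
#' split into a persistent centre-level component and month-to-month
#' variation. Sex and age percentages are drawn per centre-month; the four
#' strata counts (male/female x adult/child) are integers that add up to
#' the total by construction.
#'
#' @param centres output of [generate_centres()].
#' @param config a [generator_config()].
#' @return one row per scheduled centre-month with strata counts, totals
#'   and derived percentages.
#' @export
generate_occupancy <- function(centres, config) {
  if (nrow(centres) == 0L) stop("'centres' is empty")
  cv <- config$occupancy_sd / config$occupancy_mean
  s2 <- log1p(cv^2)
  mlog <- log(config$occupancy_mean) - s2 / 2
  s_centre <- sqrt(0.6 * s2)
  s_month <- sqrt(0.4 * s2)
  b <- rnorm(nrow(centres), 0, s_centre)
  rows <- lapply(seq_len(nrow(centres)), function(i) {
    ce <- centres[i, ]
    t <- ce$start_month + seq_len(ce$n_months) - 1L
    n <- length(t)
    tot <- pmin(config$occupancy_range[2],
                pmax(config$occupancy_range[1],
                     round_half_up(exp(mlog + b[i] + rnorm(n, 0, s_month)))))
    pm <- pmin(98, pmax(2, rnorm(n, config$male_pct_mean, config$male_pct_sd)))
    pa <- pmin(98, pmax(2, rnorm(n, config$adult_pct_mean, config$adult_pct_sd)))
    n_adult <- round_half_up(tot * pa / 100)
    n_child <- tot - n_adult
    n_male_adult <- round_half_up(n_adult * pm / 100)
    n_female_adult <- n_adult - n_male_adult
    n_male_child <- round_half_up(n_child * pm / 100)
    n_female_child <- n_child - n_male_child
    data.frame(centre_id = ce$centre_id, centre_type = ce$centre_type,
               month_index = t,
               n_male_adult = n_male_adult, n_female_adult = n_female_adult,
               n_male_child = n_male_child, n_female_child = n_female_child,
               stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, rows)
  occ$n_adult <- occ$n_male_adult + occ$n_female_adult
  occ$n_child <- occ$n_male_child + occ$n_female_child
  occ$n_occ <- occ$n_adult + occ$n_child
  occ$pct_male_occ <- 100 * (occ$n_male_adult + occ$n_male_child) / occ$n_occ
  occ$pct_adult_occ <- 100 * occ$n_adult / occ$n_occ
  occ$year_month <- index_to_ym(occ$month_index, config$epoch)
  occ
}

#' Generate patient counts from occupancy via the generating ratio model
#'
#' Draws the ratio `r` from the Gaussian mean/variance model given the
#' occupancy covariates, truncates it to (0, 1], converts it to a patient
#' count `n_pat = round(r * n_occ)` and derives patient demographics as the
#' occupancy demographics plus bounded uniform jitter. A configurable share
#' of rows is made "high-turnover" (ratio above 1, so patients exceed
#' occupancy) to exercise the downstream exclusion rule.
#'
#' @param occ output of [generate_occupancy()].
#' @param ratio_params generating [gaussian_disp_params()].
#' @param config a [generator_config()].
#' @return `occ` with patient columns and the true ratio appended.
#' @export
generate_patients <- function(occ, ratio_params, config) {
  if (nrow(occ) == 0L) stop("'occ' is empty")
  n <- nrow(occ)
  mu <- linear_predictor(ratio_params$mean, occ)
  sdv <- sqrt(exp(linear_predictor(ratio_params$logvar, occ)))
  r <- rnorm(n, mu, sdv)
  r <- pmax(pmin(r, 1), config$ratio_floor)
  if (config$high_turnover_fraction > 0) {
    k <- rbinom(1, n, config$high_turnover_fraction)
    if (k > 0) {
      ix <- sample.int(n, k)
      r[ix] <- runif(k, 1.02, 1.5)
    }
  }
  n_pat <- pmin(config$npat_max, pmax(1, round_half_up(r * occ$n_occ)))
  r <- n_pat / occ$n_occ   # exact ratio after integer rounding and capping
  j <- config$demographic_jitter
  pm <- pmin(100, pmax(0, occ$pct_male_occ + config$patient_male_shift +
                         runif(n, -j, j)))
  pa <- pmin(100, pmax(0, occ$pct_adult_occ + config$patient_adult_shift +
                         runif(n, -j, j)))
  out <- occ
  out$r_true <- r
  out$n_pat <- n_pat
  out$n_male <- round_half_up(n_pat * pm / 100)
  out$n_female <- n_pat - out$n_male
  out$n_adult_pat <- round_half_up(n_pat * pa / 100)
  out$n_minor <- n_pat - out$n_adult_pat
  out$pct_male_pat <- 100 * out$n_male / n_pat
  out$pct_adult_pat <- 100 * out$n_adult_pat / n_pat
  out
}

#' Generate disease-case counts from the zero-inflated NB2 / AR(1) model
#'
#' Per centre, a stationary latent Gaussian AR(1) series (marginal sd
#' `sigma_ar`, lag-one correlation `phi`) is simulated over the centre's
#' months and enters the conditional mean on the log scale. Each
#' observation is a structural zero with the model's logit probability,
#' otherwise NB2 with dispersion from the log-linear dispersion submodel.
#'
#' @param pat output of [generate_patients()] (ordered by centre and month).
#' @param case_params generating [zinb_ar1_params()].
#' @param config unused; kept for signature symmetry with the other
#'   generation steps.
#' @return `pat` with uncensored case counts (`n_cases_true`) and the
#'   latent values (`latent_ar1`) appended.
#' @export
generate_cases <- function(pat, case_params, config = NULL) {
  if (nrow(pat) == 0L) stop("'pat' is empty")
  ord <- order(pat$centre_id, pat$month_index)
  pat <- pat[ord, , drop = FALSE]
  eta0 <- linear_predictor(case_params$conditional, pat)
  theta <- exp(linear_predictor(case_params$dispersion, pat))
  p <- if (is.null(case_params$zi)) rep(0, nrow(pat))
       else plogis(linear_predictor(case_params$zi, pat))
  u <- numeric(nrow(pat))
  for (ix in split(seq_len(nrow(pat)), pat$centre_id)) {
    if (case_params$sigma_ar > 0)
      u[ix] <- simulate_ar1(pat$month_index[ix], case_params$sigma_ar,
                            case_params$phi)
  }
  mu <- exp(pmin(eta0 + u, 30))
  structural <- rbinom(nrow(pat), 1L, p) == 1L
  y <- rnbinom(nrow(pat), mu = mu, size = theta)
  y[structural] <- 0L
  pat$latent_ar1 <- u
  pat$structural_zero <- structural
  pat$n_cases_true <- y
  pat
}

#' Anonymisation censoring
#'
#' Exported monitoring counts below the threshold are set to 0, so a
#' reported 0 cannot be distinguished from a true 1 or 2 (with the default
#' threshold 3).
#'
#' @param counts non-negative integer vector.
#' @param threshold censoring threshold (default 3).
#' @return censored counts.
#' @examples apply_censoring(c(0, 1, 2, 3, 4))  # 0 0 0 3 4
#' @export
apply_censoring <- function(counts, threshold = 3L) {
  if (any(is.na(counts)) || any(counts < 0))
    stop("'counts' must be non-negative and complete")
  counts[counts < threshold] <- 0L
  counts
}

#' Generate a full synthetic study
#'
#' Runs the whole generative chain (occupancy, patients, cases, censoring),
#' fragments the scheduled centre-months into matched / EHR-only /
#' occupancy-only destinations with the configured probabilities, injects
#' duplicate occupancy reports, and returns the two raw streams together
#' with the ground truth.
#'
#' @param config a [generator_config()].
#' @return object of class `denomcast_study`: list with elements `ehr`
#'   (EHR stream), `occupancy` (census stream with possible duplicate
#'   reports), `truth` (full uncensored panel with latent values, true
#'   ratios and destination assignment) and `config`.
#' @export
generate_study <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  centres <- generate_centres(config, reseed = FALSE)
  occ <- generate_occupancy(centres, config)
  pat <- generate_patients(occ, config$ratio_params, config)
  panel <- generate_cases(pat, config$case_params, config)
  panel$n_cases <- apply_censoring(panel$n_cases_true, config$censor_threshold)
  dest <- sample(c("matched", "ehr_only", "occ_only"), nrow(panel),
                 replace = TRUE,
                 prob = c(config$matched_fraction, config$ehr_only_fraction,
                          config$occ_only_fraction))
  panel$destination <- dest

  ehr_rows <- panel[panel$destination != "occ_only", , drop = FALSE]
  cens <- function(x) if (config$censor_all_cells)
    apply_censoring(x, config$censor_threshold) else x
  ehr <- data.frame(centre_id = ehr_rows$centre_id,
                    year_month = ehr_rows$year_month,
                    type = ehr_rows$centre_type,
                    n_pat = cens(ehr_rows$n_pat),
                    n_male = cens(ehr_rows$n_male),
                    n_female = cens(ehr_rows$n_female),
                    n_adult = cens(ehr_rows$n_adult_pat),
                    n_minor = cens(ehr_rows$n_minor),
                    n_cases_digestive = ehr_rows$n_cases,
                    stringsAsFactors = FALSE)

  occ_rows <- panel[panel$destination != "ehr_only", , drop = FALSE]
  occ_out <- data.frame(centre_id = occ_rows$centre_id,
                        year_month = occ_rows$year_month,
                        type = occ_rows$centre_type,
                        report_id = 1L,
                        n_male_adult = occ_rows$n_male_adult,
                        n_female_adult = occ_rows$n_female_adult,
                        n_male_child = occ_rows$n_male_child,
                        n_female_child = occ_rows$n_female_child,
                        stringsAsFactors = FALSE)
  if (config$duplicate_report_rate > 0 && nrow(occ_out) > 0) {
    dup <- runif(nrow(occ_out)) < config$duplicate_report_rate
    if (any(dup)) {
      second <- occ_out[dup, , drop = FALSE]
      second$report_id <- 2L
      for (col in c("n_male_adult", "n_female_adult", "n_male_child",
                    "n_female_child")) {
        noise <- round_half_up(rnorm(nrow(second), 0,
                                     pmax(1, 0.03 * second[[col]])))
        second[[col]] <- pmax(0L, as.integer(second[[col]] + noise))
      }
      occ_out <- rbind(occ_out, second)
      occ_out <- occ_out[order(occ_out$centre_id, occ_out$year_month,
                               occ_out$report_id), , drop = FALSE]
    }
  }
  rownames(occ_out) <- NULL
  structure(list(ehr = ehr, occupancy = occ_out, truth = panel,
                 config = config),
            class = "denomcast_study")
}

#' @export
print.denomcast_study <- function(x, ...) {
  cat(sprintf("denomcast synthetic study: %d centres, %d centre-months\n",
              length(unique(x$truth$centre_id)), nrow(x$truth)))
  cat(sprintf("  EHR rows %d, occupancy reports %d (seed %d)\n",
              nrow(x$ehr), nrow(x$occupancy), x$config$seed))
  print(table(x$truth$destination))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes `ehr.csv` and `occupancy.csv` in the package's input schema plus
#' `truth.json` carrying the uncensored panel and generating parameters.
#'
#' @param study a `denomcast_study`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "denomcast_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$ehr, file.path(dir, "ehr.csv"), row.names = FALSE)
  write.csv(study$occupancy, file.path(dir, "occupancy.csv"),
            row.names = FALSE)
  truth <- list(
    panel = study$truth[, c("centre_id", "year_month", "centre_type",
                            "n_occ", "n_pat", "r_true", "latent_ar1",
                            "structural_zero", "n_cases_true", "n_cases",
                            "destination")],
    case_params = unclass_params(study$config$case_params),
    ratio_params = unclass_params(study$config$ratio_params),
    seed = study$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
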