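#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> match -> fit (relationships 1-3) ->
#' diagnose -> predict -> report. Every stage logs its record counts, all
#' dropped rows are accounted for in the exclusion log, and a manifest with
#' seeds and file hashes makes a run reproducible: the same config and seed
#' give identical outputs.
#'
#' @param config a list, or path to a YAML/JSON file, with (all optional):
#'   `scenario` - named overrides for [generator_config()] (used when no
#'   input files are given); `ehr`, `occupancy` - paths to input CSVs;
#'   `mode` - exclusion mode `"main"`, `"full"` or `"nonzero"` (in
#'   `"nonzero"` mode the zero-inflation part of the disease model is
#'   dropped); `chains` - prediction chains to run, subset of
#'   `c("patients", "occupancy", "incidence")`; `n_boot` - bootstrap draws
#'   (default 500); `n_sim` - diagnostic simulations (default 250);
#'   `seed` - master seed.
#' @param out_dir output directory.
#' @return invisibly, a list with the panel split, fits, diagnostics,
#'   predictions and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("[.]ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- modifyList(list(scenario = list(), ehr = NULL, occupancy = NULL,
                         mode = "main", chains = c("patients", "occupancy",
                                                   "incidence"),
                         n_boot = 500L, n_sim = 250L, seed = 1L),
                    config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(stage, fmt, ...) {
    msg <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- simulate or read -----------------------------------------------
  simulated <- is.null(cfg$ehr)
  if (simulated) {
    gcfg <- do.call(generator_config,
                    modifyList(list(seed = cfg$seed), cfg$scenario))
    study <- stage("simulate", generate_study(gcfg))
    write_study(study, out_dir)
    ehr_path <- file.path(out_dir, "ehr.csv")
    occ_path <- file.path(out_dir, "occupancy.csv")
    say("simulate", "%d centre-months scheduled (seed %d)",
        nrow(study$truth), gcfg$seed)
  } else {
    ehr_path <- cfg$ehr; occ_path <- cfg$occupancy
  }
  ehr <- stage("read", read_ehr(ehr_path))
  occ_raw <- stage("read", read_occupancy(occ_path))
  say("read", "EHR rows %d, occupancy reports %d", nrow(ehr), nrow(occ_raw))

  # --- match ----------------------------------------------------------
  occ <- stage("match", aggregate_duplicates(occ_raw))
  say("match", "occupancy reports aggregated to %d centre-months", nrow(occ))
  split <- stage("match", match_panels(ehr, occ))
  n_before <- nrow(split$matched)
  split <- stage("match", apply_exclusions(split, cfg$mode))
  say("match", "matched %d (of %d before exclusions, mode=%s), EHR-unmatched %d, occupancy-unmatched %d",
      nrow(split$matched), n_before, cfg$mode, nrow(split$ehr_unmatched),
      nrow(split$occ_unmatched))
  write.csv(split$matched, file.path(out_dir, "matched.csv"),
            row.names = FALSE)
  write.csv(split$ehr_unmatched, file.path(out_dir, "ehr_unmatched.csv"),
            row.names = FALSE)
  write.csv(split$occ_unmatched, file.path(out_dir, "occ_unmatched.csv"),
            row.names = FALSE)
  write.csv(split$exclusions, file.path(out_dir, "exclusions.log"),
            row.names = FALSE)

  subsets <- list(ehr = split$ehr_all, occupancy = split$occ_all,
                  matched = split$matched,
                  ehr_unmatched = split$ehr_unmatched,
                  occ_unmatched = split$occ_unmatched)
  for (nm in names(subsets)) {
    de <- describe_panel(subsets[[nm]])
    write.csv(de, file.path(out_dir, paste0("describe_", nm, ".csv")),
              row.names = FALSE)
  }

  # --- fit ------------------------------------------------------------
  ehr_fit_data <- split$ehr_all
  variant <- "full"
  if (cfg$mode == "nonzero") {
    keep <- ehr_fit_data$n_cases > 0
    say("fit", "dropping %d zero-case EHR rows for the nonzero variant",
        sum(!keep))
    ehr_fit_data <- ehr_fit_data[keep, , drop = FALSE]
    variant <- "no_zi"
  }
  fit1 <- stage("fit", fit_relationship1(ehr_fit_data, variant = variant))
  fit2 <- stage("fit", fit_relationship2(split$matched))
  fit3 <- stage("fit", fit_relationship3(split$matched))
  say("fit", "relationship 1: loglik %.1f AIC %.1f; 2: AIC %.1f; 3: AIC %.1f",
      fit1$loglik, fit1$AIC, fit2$AIC, fit3$AIC)
  write_fit_json(fit1, file.path(out_dir, "fit1.json"))
  write_fit_json(fit2, file.path(out_dir, "fit2.json"))
  write_fit_json(fit3, file.path(out_dir, "fit3.json"))

  # --- diagnose -------------------------------------------------------
  diags <- stage("diagnose", list(
    relationship2 = quantile_residuals(fit2, split$matched,
                                       n_sim = cfg$n_sim, seed = cfg$seed),
    relationship3 = quantile_residuals(fit3, split$matched,
                                       n_sim = cfg$n_sim,
                                       seed = cfg$seed + 1L)))
  say("diagnose", "KS p-values: rel2 %.3f, rel3 %.3f",
      diags$relationship2$ks_p_value, diags$relationship3$ks_p_value)

  # --- predict --------------------------------------------------------
  preds <- list()
  if ("patients" %in% cfg$chains && nrow(split$occ_unmatched) > 0)
    preds$patients <- stage("predict",
      predict_patients(fit2, split$occ_unmatched, n_boot = cfg$n_boot,
                       seed = cfg$seed))
  if ("occupancy" %in% cfg$chains && nrow(split$ehr_unmatched) > 0)
    preds$occupancy <- stage("predict",
      predict_occupancy(fit3, split$ehr_unmatched, n_boot = cfg$n_boot,
                        seed = cfg$seed))
  if ("incidence" %in% cfg$chains && nrow(split$occ_unmatched) > 0)
    preds$incidence <- stage("predict",
      predict_incidence_wrt_occupancy(fit1, fit2, split$occ_unmatched,
                                      n_boot = cfg$n_boot,
                                      seed = cfg$seed))
  if (length(preds)) {
    allp <- do.call(rbind, lapply(preds, function(p)
      p[, c("centre_id", "year_month", "target", "point", "lower95",
            "upper95", "method", "flags")]))
    write.csv(allp, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    say("predict", "%d predictions written", nrow(allp))
  }

  # --- report ---------------------------------------------------------
  report <- c(
    "# denomcast pipeline report", "",
    sprintf("- mode: %s, seed: %d, simulated inputs: %s", cfg$mode,
            cfg$seed, simulated),
    sprintf("- subsets: EHR %d | occupancy %d | matched %d | EHR-unmatched %d | occupancy-unmatched %d",
            nrow(split$ehr_all), nrow(split$occ_all), nrow(split$matched),
            nrow(split$ehr_unmatched), nrow(split$occ_unmatched)),
    sprintf("- exclusions: %d (see exclusions.log)", nrow(split$exclusions)),
    "", "## Model fits", "")
  for (f in list(fit1, fit2, fit3)) {
    report <- c(report,
                sprintf("### %s (n = %d, AIC = %.1f)", f$relationship,
                        f$n_obs, f$AIC), "",
                knit_table(wald_ci(f)), "")
  }
  report <- c(report, "## Diagnostics", "",
              sprintf("- relationship 2: KS D = %.3f (p = %.3f), dispersion ratio %.2f, outliers %d",
                      diags$relationship2$ks_statistic,
                      diags$relationship2$ks_p_value,
                      diags$relationship2$dispersion_ratio,
                      diags$relationship2$n_outliers),
              sprintf("- relationship 3: KS D = %.3f (p = %.3f), dispersion ratio %.2f, outliers %d",
                      diags$relationship3$ks_statistic,
                      diags$relationship3$ks_p_value,
                      diags$relationship3$dispersion_ratio,
                      diags$relationship3$n_outliers),
              "", "## Log", "", paste0("    ", log_lines))
  writeLines(report, file.path(out_dir, "report.md"))

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "denomcast",
    version = as.character(utils::packageVersion("denomcast")),
    seed = cfg$seed, mode = cfg$mode, simulated = simulated,
    counts = lapply(subsets, nrow),
    exclusions = nrow(split$exclusions),
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(split = split, fits = list(fit1 = fit1, fit2 = fit2,
                                            fit3 = fit3),
                 diagnostics = diags, predictions = preds,
                 manifest = manifest))
}

# minimal markdown table
knit_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) sprintf("%.4g", x) else as.character(x)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
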