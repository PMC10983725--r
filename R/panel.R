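# Reading, deduplicating, matching and summarising the two data streams.

read_stream <- function(path, required, count_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("missing columns in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  for (col in count_cols) {
    x <- d[[col]]
    bad <- which(is.na(x) | x < 0 | x != round(x))
    if (length(bad))
      stop("non-integer or negative count in ", basename(path),
           ", column '", col, "', row(s) ",
           paste(head(bad, 5), collapse = ", "))
    d[[col]] <- as.integer(x)
  }
  badym <- which(!grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", d$year_month))
  if (length(badym))
    stop("unparseable year_month in ", basename(path), ", row(s) ",
         paste(head(badym, 5), collapse = ", "))
  d
}

#' Read the EHR monitoring export
#'
#' Expects the columns `centre_id, year_month, type, n_pat, n_male,
#' n_female, n_adult, n_minor, n_cases_digestive`. Counts must be
#' non-negative integers and `year_month` ISO `"YYYY-MM"`; malformed rows
#' are reported with their row numbers. Derived patient percentages and the
#' month index are added; a flag marks rows whose demographic cells were
#' apparently censored (zero cell with positive total).
#'
#' @param path CSV file path.
#' @param epoch epoch month for [ym_to_index()].
#' @return data frame of typed EHR centre-month records.
#' @export
read_ehr <- function(path, epoch = "2017-11") {
  d <- read_stream(path,
                   required = c("centre_id", "year_month", "type", "n_pat",
                                "n_male", "n_female", "n_adult", "n_minor",
                                "n_cases_digestive"),
                   count_cols = c("n_pat", "n_male", "n_female", "n_adult",
                                  "n_minor", "n_cases_digestive"))
  out <- data.frame(centre_id = as.character(d$centre_id),
                    year_month = d$year_month,
                    centre_type = as.character(d$type),
                    n_pat = d$n_pat, n_male = d$n_male,
                    n_female = d$n_female, n_adult = d$n_adult,
                    n_minor = d$n_minor, n_cases = d$n_cases_digestive,
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$centre_type), c("REC", "REG"))
  if (length(bad)) stop("unknown centre type(s): ", paste(bad, collapse = ", "))
  out$month_index <- ym_to_index(out$year_month, epoch)
  out$pct_male_pat <- ifelse(out$n_pat > 0, 100 * out$n_male / out$n_pat, NA)
  out$pct_adult_pat <- ifelse(out$n_pat > 0, 100 * out$n_adult / out$n_pat, NA)
  out$demog_censored <- out$n_pat > 0 &
    ((out$n_male == 0 & out$n_female == 0) |
     (out$n_adult == 0 & out$n_minor == 0))
  out
}

#' Read the occupancy census export
#'
#' Expects `centre_id, year_month, report_id, n_male_adult, n_female_adult,
#' n_male_child, n_female_child` and (optionally) a `type` column; multiple
#' reports per centre-month are allowed and are reduced by
#' [aggregate_duplicates()]. Totals and percentages are added by
#' [compute_totals()].
#'
#' @inheritParams read_ehr
#' @return data frame of occupancy report records.
#' @export
read_occupancy <- function(path, epoch = "2017-11") {
  d <- read_stream(path,
                   required = c("centre_id", "year_month", "report_id",
                                "n_male_adult", "n_female_adult",
                                "n_male_child", "n_female_child"),
                   count_cols = c("report_id", "n_male_adult",
                                  "n_female_adult", "n_male_child",
                                  "n_female_child"))
  out <- data.frame(centre_id = as.character(d$centre_id),
                    year_month = d$year_month,
                    report_id = d$report_id,
                    n_male_adult = d$n_male_adult,
                    n_female_adult = d$n_female_adult,
                    n_male_child = d$n_male_child,
                    n_female_child = d$n_female_child,
                    stringsAsFactors = FALSE)
  if ("type" %in% names(d)) {
    out$centre_type <- as.character(d$type)
    bad <- setdiff(unique(out$centre_type), c("REC", "REG"))
    if (length(bad)) stop("unknown centre type(s): ",
                          paste(bad, collapse = ", "))
  }
  out$month_index <- ym_to_index(out$year_month, epoch)
  out
}

#' Average duplicate occupancy reports
#'
#' Where a centre-month has more than one occupancy report, each stratum is
#' replaced by the arithmetic mean across reports, rounded half away from
#' zero to a natural number; totals are recomputed from the rounded strata.
#' Idempotent: applying it twice changes nothing.
#'
#' @param occ output of [read_occupancy()] (or same-shaped data).
#' @return one record per centre-month, with totals and percentages.
#' @export
aggregate_duplicates <- function(occ) {
  strata <- c("n_male_adult", "n_female_adult", "n_male_child",
              "n_female_child")
  key <- interaction(occ$centre_id, occ$year_month, drop = TRUE)
  first <- !duplicated(key)
  agg <- occ[first, setdiff(names(occ), c("report_id", strata)),
             drop = FALSE]
  for (col in strata) {
    m <- tapply(occ[[col]], key, mean)
    agg[[col]] <- as.integer(round_half_up(m[as.character(key[first])]))
  }
  agg$n_reports <- as.integer(table(key)[as.character(key[first])])
  rownames(agg) <- NULL
  compute_totals(agg)
}

#' Derive occupancy totals and percentages from strata counts
#'
#' Adults are the sum of male and female adults, children likewise, and the
#' total occupancy their sum; male and adult percentages are derived.
#' Rows with zero total occupancy get `NA` percentages and a flag.
#'
#' @param occ data frame with the four strata columns.
#' @return `occ` with `n_adult_occ`, `n_child_occ`, `n_occ`,
#'   `pct_male_occ`, `pct_adult_occ` and `degenerate_occ` columns.
#' @export
compute_totals <- function(occ) {
  strata <- c("n_male_adult", "n_female_adult", "n_male_child",
              "n_female_child")
  miss <- setdiff(strata, names(occ))
  if (length(miss))
    stop("missing occupancy strata column(s): ", paste(miss, collapse = ", "))
  occ$n_adult_occ <- occ$n_male_adult + occ$n_female_adult
  occ$n_child_occ <- occ$n_male_child + occ$n_female_child
  occ$n_occ <- occ$n_adult_occ + occ$n_child_occ
  occ$pct_male_occ <- ifelse(occ$n_occ > 0,
                             100 * (occ$n_male_adult + occ$n_male_child) /
                               occ$n_occ, NA)
  occ$pct_adult_occ <- ifelse(occ$n_occ > 0,
                              100 * occ$n_adult_occ / occ$n_occ, NA)
  occ$degenerate_occ <- occ$n_occ == 0
  occ
}

#' Match the EHR and occupancy streams on centre and month
#'
#' Inner join on `centre_id` x `year_month`: matched centre-months carry
#' both blocks and the ratio `r = n_pat / n_occ`; EHR rows without a
#' partner form the EHR-unmatched set, occupancy rows without a partner the
#' occupancy-unmatched set. Duplicate occupancy reports must already be
#' aggregated. A centre reported with conflicting types across streams is
#' an error.
#'
#' @param ehr output of [read_ehr()].
#' @param occ output of [aggregate_duplicates()].
#' @return object of class `panel_split`: list with `matched`,
#'   `ehr_unmatched`, `occ_unmatched`, `ehr_all`, `occ_all` and an (empty)
#'   `exclusions` log.
#' @export
match_panels <- function(ehr, occ) {
  if (anyDuplicated(paste(occ$centre_id, occ$year_month)))
    stop("occupancy records contain duplicate centre-months; run ",
         "aggregate_duplicates() first")
  if ("centre_type" %in% names(occ)) {
    both <- merge(unique(ehr[, c("centre_id", "centre_type")]),
                  unique(occ[, c("centre_id", "centre_type")]),
                  by = "centre_id")
    bad <- both$centre_id[both$centre_type.x != both$centre_type.y]
    if (length(bad))
      stop("conflicting centre_type across streams for centre(s): ",
           paste(unique(bad), collapse = ", "))
  }
  occ_cols <- setdiff(names(occ), c("centre_type"))
  m <- merge(ehr, occ[, occ_cols], by = c("centre_id", "year_month"),
             suffixes = c("", ".occ"))
  m$month_index <- m$month_index  # from EHR side
  m$month_index.occ <- NULL
  m$r <- ifelse(m$n_occ > 0, m$n_pat / m$n_occ, NA)
  key_e <- paste(ehr$centre_id, ehr$year_month)
  key_o <- paste(occ$centre_id, occ$year_month)
  key_m <- paste(m$centre_id, m$year_month)
  ehr_un <- ehr[!key_e %in% key_m, , drop = FALSE]
  occ_un <- occ[!key_o %in% key_m, , drop = FALSE]
  rownames(ehr_un) <- rownames(occ_un) <- NULL
  structure(list(matched = m, ehr_unmatched = ehr_un,
                 occ_unmatched = occ_un, ehr_all = ehr, occ_all = occ,
                 exclusions = data.frame(centre_id = character(0),
                                         year_month = character(0),
                                         reason = character(0))),
            class = "panel_split")
}

#' @export
print.panel_split <- function(x, ...) {
  cat("denomcast panel split\n")
  cat(sprintf("  EHR %d | occupancy %d | matched %d | EHR-unmatched %d | occupancy-unmatched %d\n",
              nrow(x$ehr_all), nrow(x$occ_all), nrow(x$matched),
              nrow(x$ehr_unmatched), nrow(x$occ_unmatched)))
  if (nrow(x$exclusions))
    cat(sprintf("  exclusions logged: %d\n", nrow(x$exclusions)))
  invisible(x)
}

#' Apply the analysis exclusion rules to the matched data
#'
#' Mode `"main"` drops centre-months whose occupancy is smaller than the
#' patient count (plausible only under high turnover, and incompatible with
#' occupancy as population at risk); `"full"` keeps everything (sensitivity
#' analysis on the complete matched set); `"nonzero"` additionally drops
#' rows with zero reported cases (the censoring-sensitivity analysis, fitted
#' without the zero-inflation part). Every dropped row is logged with its
#' reason; nothing is silently deleted.
#'
#' @param x a `panel_split` or a matched data frame with `n_pat`, `n_occ`
#'   and `n_cases` columns.
#' @param mode `"main"`, `"full"` or `"nonzero"`.
#' @return for a `panel_split` input, the split with a filtered `matched`
#'   set and an appended exclusion log; for a data frame, a list with
#'   `data` and `exclusions`.
#' @export
apply_exclusions <- function(x, mode = c("main", "full", "nonzero")) {
  mode <- match.arg(mode)
  m <- if (inherits(x, "panel_split")) x$matched else x
  drop <- rep(FALSE, nrow(m))
  reason <- character(nrow(m))
  if (mode %in% c("main", "nonzero")) {
    occ_lt_pat <- m$n_occ < m$n_pat
    drop <- drop | occ_lt_pat
    reason[occ_lt_pat] <- "occ<pat"
  }
  if (mode == "nonzero") {
    zero <- !drop & m$n_cases == 0
    drop <- drop | zero
    reason[zero] <- "zero cases"
  }
  log <- data.frame(centre_id = m$centre_id[drop],
                    year_month = m$year_month[drop],
                    reason = reason[drop], stringsAsFactors = FALSE)
  kept <- m[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  if (inherits(x, "panel_split")) {
    x$matched <- kept
    x$exclusions <- rbind(x$exclusions, log)
    x
  } else list(data = kept, exclusions = log)
}

#' Summarise a dataset in the descriptive-table layout
#'
#' Per numeric variable: N, number missing, mean, sd, median, first and
#' third quartile (linear-interpolation quantiles), minimum and maximum.
#' Per categorical variable: level counts and percentages.
#'
#' @param data data frame.
#' @param variables columns to describe (default: all except identifiers).
#' @return data frame in long layout, one row per variable (or level).
#' @export
describe_panel <- function(data, variables = NULL) {
  if (nrow(data) == 0L) {
    warning("empty dataset: returning empty description", call. = FALSE)
    return(data.frame(variable = character(0)))
  }
  if (is.null(variables))
    variables <- setdiff(names(data),
                         c("centre_id", "year_month", "month_index",
                           "report_id"))
  out <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.numeric(x)) {
      xx <- x[!is.na(x)]
      q <- if (length(xx)) quantile(xx, c(0.25, 0.5, 0.75), type = 7)
           else rep(NA_real_, 3)
      out[[v]] <- data.frame(
        variable = v, level = NA_character_, n = length(xx),
        n_missing = sum(is.na(x)),
        mean = if (length(xx)) mean(xx) else NA_real_,
        sd = if (length(xx) > 1) sd(xx) else if (length(xx) == 1) 0 else NA_real_,
        median = q[2], q1 = q[1], q3 = q[3],
        min = if (length(xx)) min(xx) else NA_real_,
        max = if (length(xx)) max(xx) else NA_real_,
        count = NA_integer_, pct = NA_real_, stringsAsFactors = FALSE)
    } else {
      tb <- table(x, useNA = "no")
      out[[v]] <- data.frame(
        variable = v, level = names(tb), n = sum(tb),
        n_missing = sum(is.na(x)), mean = NA_real_, sd = NA_real_,
        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
        min = NA_real_, max = NA_real_,
        count = as.integer(tb), pct = 100 * as.integer(tb) / length(x),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
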