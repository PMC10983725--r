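# Stream IO, duplicate aggregation, matching, exclusions and description.

write_streams <- function(seed = 7, n_centres = 15, ...) {
  st <- generate_study(generator_config(seed = seed, n_centres = n_centres,
                                        ...))
  dir <- tempfile("study")
  write_study(st, dir)
  list(study = st, dir = dir)
}

test_that("CSV readers type records and report malformed rows", {
  ws <- write_streams()
  ehr <- read_ehr(file.path(ws$dir, "ehr.csv"))
  occ <- read_occupancy(file.path(ws$dir, "occupancy.csv"))
  expect_equal(nrow(ehr), nrow(ws$study$ehr))
  expect_equal(nrow(occ), nrow(ws$study$occupancy))
  expect_true(all(ehr$centre_type %in% c("REC", "REG")))
  # malformed inputs
  bad <- tempfile(fileext = ".csv")
  writeLines(c("centre_id,year_month,type,n_pat,n_male,n_female,n_adult,n_minor,n_cases_digestive",
               "C01,2018-01,REC,10,5,5,8,2,-3"), bad)
  expect_error(read_ehr(bad), "row\\(s\\) 1")
  writeLines(c("centre_id,year_month,type,n_pat,n_male,n_female,n_adult,n_minor,n_cases_digestive",
               "C01,January,REC,10,5,5,8,2,3"), bad)
  expect_error(read_ehr(bad), "year_month")
  writeLines("centre_id,year_month", bad)
  expect_error(read_ehr(bad), "missing columns")
  # empty file with header -> empty collection
  writeLines("centre_id,year_month,type,n_pat,n_male,n_female,n_adult,n_minor,n_cases_digestive",
             bad)
  expect_equal(nrow(read_ehr(bad)), 0L)
})

test_that("duplicate occupancy reports are averaged and rounded half-up", {
  occ <- data.frame(centre_id = "A", year_month = "2019-02",
                    report_id = c(1L, 2L),
                    n_male_adult = c(10L, 13L), n_female_adult = c(4L, 4L),
                    n_male_child = c(0L, 1L), n_female_child = c(2L, 3L),
                    month_index = 15L, stringsAsFactors = FALSE)
  agg <- aggregate_duplicates(occ)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$n_male_adult, 12L)   # 11.5 rounds away from zero
  expect_equal(agg$n_female_adult, 4L)
  expect_equal(agg$n_male_child, 1L)    # 0.5 -> 1
  expect_equal(agg$n_female_child, 3L)  # 2.5 -> 3
  expect_equal(agg$n_occ, 20L)
  # idempotent; single and triplicate reports
  agg2 <- aggregate_duplicates(agg)
  expect_equal(agg2$n_occ, agg$n_occ)
  tri <- occ[c(1, 1, 1), ]; tri$report_id <- 1:3
  tri$n_male_adult <- c(4L, 4L, 4L)
  expect_equal(aggregate_duplicates(tri)$n_male_adult, 4L)
})

test_that("occupancy totals and percentages follow the stated arithmetic", {
  occ <- data.frame(n_male_adult = 100L, n_female_adult = 80L,
                    n_male_child = 30L, n_female_child = 40L)
  tot <- compute_totals(occ)
  expect_equal(tot$n_adult_occ, 180L)
  expect_equal(tot$n_child_occ, 70L)
  expect_equal(tot$n_occ, 250L)
  expect_equal(tot$pct_adult_occ, 72)
  expect_equal(tot$pct_male_occ, 52)
  zero <- compute_totals(occ * 0L)
  expect_true(is.na(zero$pct_male_occ) && zero$degenerate_occ)
  one <- compute_totals(data.frame(n_male_adult = 1L, n_female_adult = 0L,
                                   n_male_child = 0L, n_female_child = 0L))
  expect_equal(one$pct_male_occ, 100)
  expect_error(compute_totals(occ[, -1]), "strata")
})

test_that("matching has inner-join semantics with unmatched remainders", {
  ehr <- data.frame(centre_id = "A", year_month = c("2018-01", "2018-02"),
                    centre_type = "REC", n_pat = c(50L, 60L), n_male = 30L,
                    n_female = 20L, n_adult = 40L, n_minor = 10L,
                    n_cases = c(5L, 6L), month_index = 2:3,
                    pct_male_pat = 50, pct_adult_pat = 80,
                    stringsAsFactors = FALSE)
  occ <- data.frame(centre_id = "A", year_month = c("2018-02", "2018-03"),
                    n_male_adult = 60L, n_female_adult = 40L,
                    n_male_child = 10L, n_female_child = 10L,
                    month_index = 3:4, stringsAsFactors = FALSE)
  occ <- compute_totals(occ)
  sp <- match_panels(ehr, occ)
  expect_equal(sp$matched$year_month, "2018-02")
  expect_equal(sp$ehr_unmatched$year_month, "2018-01")
  expect_equal(sp$occ_unmatched$year_month, "2018-03")
  expect_equal(sp$matched$r, 60 / 120)
  # disjoint months -> empty matched
  occ2 <- occ; occ2$year_month <- c("2020-01", "2020-02")
  expect_equal(nrow(match_panels(ehr, occ2)$matched), 0L)
  # conflicting types across streams
  occ3 <- occ; occ3$centre_type <- "REG"
  expect_error(match_panels(ehr, occ3), "conflicting centre_type")
})

test_that("exclusion modes drop and log the right rows", {
  m <- data.frame(centre_id = c("A", "B", "C"),
                  year_month = "2019-01",
                  n_pat = c(60L, 50L, 40L), n_occ = c(40L, 100L, 90L),
                  n_cases = c(4L, 0L, 3L))
  main <- apply_exclusions(m, "main")
  expect_equal(main$data$centre_id, c("B", "C"))
  expect_equal(main$exclusions$reason, "occ<pat")
  full <- apply_exclusions(m, "full")
  expect_equal(nrow(full$data), 3L)
  expect_equal(nrow(full$exclusions), 0L)
  nz <- apply_exclusions(m, "nonzero")
  expect_equal(nz$data$centre_id, "C")
  expect_setequal(nz$exclusions$reason, c("occ<pat", "zero cases"))
  expect_error(apply_exclusions(m, "bogus"))
})

test_that("split accounting round-trips: nothing vanishes unlogged", {
  ws <- write_streams(seed = 9, n_centres = 25)
  ehr <- read_ehr(file.path(ws$dir, "ehr.csv"))
  occ <- aggregate_duplicates(read_occupancy(file.path(ws$dir,
                                                       "occupancy.csv")))
  sp <- match_panels(ehr, occ)
  n_matched_before <- nrow(sp$matched)
  expect_equal(nrow(sp$ehr_all), n_matched_before + nrow(sp$ehr_unmatched))
  expect_equal(nrow(sp$occ_all), n_matched_before + nrow(sp$occ_unmatched))
  sp2 <- apply_exclusions(sp, "main")
  expect_equal(nrow(sp2$matched) + nrow(sp2$exclusions), n_matched_before)
  # survivors of main mode satisfy the ratio bound
  expect_true(all(sp2$matched$r <= 1 & sp2$matched$r > 0))
})

test_that("describe produces the descriptive-table layout", {
  d <- data.frame(x = c(1, 2, 3, 4), g = c("REC", "REC", "REG", "REC"))
  tab <- describe_panel(d)
  xrow <- tab[tab$variable == "x", ]
  expect_equal(xrow$mean, 2.5)
  expect_equal(xrow$sd, sd(1:4), tolerance = 1e-10)
  expect_equal(xrow$median, 2.5)
  expect_equal(c(xrow$q1, xrow$q3), c(1.75, 3.25))
  grow <- tab[tab$variable == "g", ]
  expect_equal(grow$count[grow$level == "REC"], 3L)
  expect_equal(grow$pct[grow$level == "REG"], 25)
  expect_equal(describe_panel(data.frame(k = rep(7, 5)))$sd, 0)
  expect_warning(describe_panel(data.frame()), "empty")
})

test_that("generator truth flows through description (incidence near 0.092)", {
  st <- generate_study(generator_config(seed = 13, n_centres = 120))
  ehr <- st$ehr
  inc <- ehr$n_cases_digestive / ehr$n_pat
  tab <- describe_panel(data.frame(incidence = inc))
  expect_lt(abs(tab$mean - 0.092), 0.015)
})
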