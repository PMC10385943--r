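test_that("cohort construction validates invariants with addressed errors", {
  co <- tiny_cohort()
  expect_s3_class(co, "icu_cohort")
  expect_equal(nrow(co$days), 6)

  dup <- co$days[c(1:6, 2), ]
  expect_error(icu_cohort(co$baselines, dup), "p1/2",
               class = "albumsm_integrity_error")

  expect_error(icu_cohort(co$baselines, co$days[, setdiff(names(co$days), "day")]),
               "day", class = "albumsm_schema_error")

  gap <- co$days[-2, ]  # p1 now has days 1, 3
  expect_error(icu_cohort(co$baselines, gap), "consecutive",
               class = "albumsm_integrity_error")

  two_events <- co$days
  two_events$event[2] <- TRUE
  expect_error(icu_cohort(co$baselines, two_events), "more than one event",
               class = "albumsm_integrity_error")

  # rows beyond the horizon are administratively truncated, not an error
  long <- co$days
  long$day[6] <- 30L
  trunc <- icu_cohort(co$baselines, long)
  expect_equal(nrow(trunc$days), 5)
  expect_true(all(trunc$days$day <= 28))
})

test_that("cohort csv round-trip is lossless", {
  co <- small_sim(n = 40, seed = 7)
  dp <- withr::local_tempfile(fileext = ".csv")
  bp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, dp, bp)
  back <- read_cohort(dp, bp)
  expect_equal(nrow(back$days), nrow(co$days))
  num <- vapply(co$days, is.numeric, logical(1))
  expect_equal(as.data.frame(back$days[num]), as.data.frame(co$days[num]),
               tolerance = 1e-12)
  expect_equal(back$days$treated, co$days$treated)

  # byte-identical write(read(f)) on a fixture with exact decimal values
  co2 <- tiny_cohort()
  d1 <- withr::local_tempfile(fileext = ".csv")
  b1 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co2, d1, b1)
  d2 <- withr::local_tempfile(fileext = ".csv")
  b2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(read_cohort(d1, b1), d2, b2)
  expect_identical(readLines(d1), readLines(d2))
  expect_identical(readLines(b1), readLines(b2))
})

test_that("schema mapping renames file columns to canonical names", {
  co <- tiny_cohort()
  dp <- withr::local_tempfile(fileext = ".csv")
  bp <- withr::local_tempfile(fileext = ".csv")
  days2 <- dplyr::rename(co$days, icudayseq = day)
  readr::write_csv(days2, dp)
  readr::write_csv(co$baselines, bp)
  back <- read_cohort(dp, bp, schema = c(day = "icudayseq"))
  expect_equal(back$days$day, co$days$day)
})

test_that("inclusion filters implement the study exclusions in order", {
  b <- tibble::tibble(
    patient_id = paste0("p", 1:6),
    icu_los = c(20, 72, 72, 2500, 72, 72),
    hospital_los = c(120, 20, 120, 3000, 120, 120),
    icu_admit_time = 0,
    sepsis_onset_time = c(0, 0, 40, 0, -2, 0),
    icu_stay_index = c(1, 1, 1, 1, 1, 2)
  )
  d <- tibble::tibble(patient_id = rep(b$patient_id, each = 2), day = rep(1:2, 6))
  co <- icu_cohort(b, d)
  out <- apply_inclusion_filters(co)
  # p1 icu_los 20h out; p2 hospital 20h out; p3 onset +40h out; p4 icu 2500h out;
  # p5 onset -2h retained; p6 second stay out
  expect_setequal(out$baselines$patient_id, "p5")
  tally <- exclusion_tally(out)
  expect_equal(tally$n_excluded[tally$criterion == "icu_los<24h"], 1)
  expect_equal(tally$n_excluded[tally$criterion == "hospital_los<24h"], 1)
  expect_equal(sum(tally$n_excluded), 5)

  # idempotence
  again <- apply_inclusion_filters(out)
  expect_identical(again$baselines, out$baselines)
  expect_identical(again$days, out$days)

  # all-pass cohort is untouched
  ok <- icu_cohort(b[5, ], d[d$patient_id == "p5", ])
  expect_identical(apply_inclusion_filters(ok)$days, ok$days)
})

test_that("daily worst-value collapsing follows the direction map", {
  m <- tibble::tibble(
    patient_id = "p1", day = 3,
    variable = c("map", "map", "map", "lactate", "lactate", "sofa"),
    value = c(70, 55, 65, 1.5, 3.2, 2)
  )
  out <- collapse_daily_worst(m)
  expect_equal(out$map, 55)       # lower MAP is worse
  expect_equal(out$lactate, 3.2)  # higher lactate is worse
  expect_equal(out$sofa, 2)       # singleton

  # permutation invariance
  out2 <- collapse_daily_worst(m[sample(nrow(m)), ])
  expect_equal(out2[names(out)], out)

  expect_error(collapse_daily_worst(tibble::tibble(
    patient_id = "p", day = 1, variable = "mystery", value = 1)),
    "mystery", class = "albumsm_config_error")
})

test_that("albumin dose formula and strata match the dosing conventions", {
  # 100 mL of 25% + 500 mL of 5% at 80 kg = (25 + 25)/80
  expect_equal(compute_albumin_dose(c(100, 500), c(0.25, 0.05), 80), 0.625)
  expect_equal(compute_albumin_dose(numeric(), numeric(), 80), 0)
  expect_error(compute_albumin_dose(-10, 0.25, 80), class = "albumsm_input_error")
  expect_error(compute_albumin_dose(100, 1.5, 80), class = "albumsm_input_error")
  expect_error(compute_albumin_dose(100, 0.25, 0), class = "albumsm_input_error")

  # dose additivity over concatenated infusion lists
  a <- compute_albumin_dose(c(100, 50), c(0.25, 0.05), 70)
  b <- compute_albumin_dose(c(200), c(0.05), 70)
  expect_equal(compute_albumin_dose(c(100, 50, 200), c(0.25, 0.05, 0.05), 70), a + b)

  # strata: upper-closed boundaries, monotone, partition of [0, Inf)
  expect_equal(as.character(dose_stratum(c(0, 0.5, 0.625, 1.0, 1.2, 1.5, 1.51))),
               c("none", "low", "mid", "mid", "high", "high", "vhigh"))
  doses <- sort(runif(100, 0, 3))
  s <- as.integer(dose_stratum(doses))
  expect_true(all(diff(s) >= 0))
  expect_false(anyNA(dose_stratum(c(0, 10, 1e6))))
})

test_that("NEE conversion sums rate-weighted factors", {
  expect_equal(compute_nee(c(norepinephrine = 0.1)), 0.1)
  expect_equal(compute_nee(numeric()), 0)
  expect_equal(compute_nee(c(norepinephrine = 0.1, epinephrine = 0.05),
                           conversion = c(norepinephrine = 1, epinephrine = 1)),
               0.15)
  expect_equal(compute_nee(c(dopamine = 10)), 0.1)
  expect_error(compute_nee(c(unknowndrug = 1)), class = "albumsm_config_error")
  expect_error(compute_nee(c(norepinephrine = -0.1)), class = "albumsm_input_error")
})

test_that("septic shock requires vasopressors and lactate strictly above 2", {
  d <- tibble::tibble(vaso_nee = c(0.1, 0.1, 0, 0.1),
                      lactate = c(2.1, 2.0, 5.0, NA))
  out <- flag_septic_shock(d)
  expect_equal(out$septic_shock, c(TRUE, FALSE, FALSE, NA))
})
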