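test_that("sub-cohort membership follows the first-infusion-day rule", {
  co <- tiny_cohort()  # p1 first treated day 2 with serum albumin 2.6; p2 never
  r1 <- indication_rule("serum_albumin", 2.5, 3.0)
  sub <- build_subcohort(co, r1)
  expect_setequal(sub$baselines$patient_id, c("p1", "p2"))
  expect_equal(sub$meta$indication$n_treated, 1)
  expect_equal(sub$meta$indication$n_comparator, 1)

  r2 <- indication_rule("serum_albumin", -Inf, 2.5)
  expect_warning(sub2 <- build_subcohort(co, r2), "empty treated arm")
  expect_false(sub2$meta$estimable)
  # never-treated comparator present in every sub-cohort
  expect_true("p2" %in% sub2$baselines$patient_id)
})

test_that("prespecified albumin bins partition treated patients; comparator fixed", {
  co <- small_sim(n = 400, seed = 71)
  bins <- albumin_indication_bins()
  subs <- purrr::map(bins, ~ suppressWarnings(build_subcohort(co, .x)))
  os <- outcome_summary(co)
  treated_ids <- os$patient_id[os$ever_treated]
  never_ids <- os$patient_id[!os$ever_treated]

  arm_ids <- purrr::map(subs, ~ .x$meta$indication$treated_ids)
  all_assigned <- sort(unlist(arm_ids))
  expect_equal(all_assigned, sort(treated_ids))      # union + disjoint
  expect_equal(anyDuplicated(all_assigned), 0)

  # comparator arm identical across sub-cohorts, fully present in each panel
  for (s in subs) {
    expect_setequal(s$meta$indication$comparator_ids, never_ids)
    expect_true(all(never_ids %in% s$baselines$patient_id))
    # off-rule initiators contribute no treated person-time
    treated_days <- s$days$patient_id[s$days$treated]
    expect_true(all(treated_days %in% s$meta$indication$treated_ids))
  }
})

test_that("indication evaluation runs the weighted pipeline inside the sub-cohort", {
  co <- small_sim(n = 600, seed = 72)
  sub <- build_subcohort(co, indication_rule("serum_albumin", -Inf, 3.2))
  fit <- suppressWarnings(evaluate_indication(sub, n_family = 5))
  expect_s3_class(fit, "mscm_fit")
  td <- tidy(fit)
  expect_true(td$conf.low[1] < td$hr[1] & td$hr[1] < td$conf.high[1])
  expect_type(fit$indication$p_adjusted_significant, "logical")
})

test_that("threshold searches stop at the first failing threshold", {
  co <- simulate_cohort(sim_scenario("albumin_threshold", n_patients = 1500),
                        seed = 73)
  res <- albumin_threshold_search(co)
  tr <- res$trace
  # monotone-stop property: no qualifying threshold beyond the returned one
  if (!is.na(res$threshold)) {
    expect_equal(max(tr$threshold[tr$qualifies]), res$threshold)
    expect_true(all(tr$qualifies[-nrow(tr)]))
  } else {
    expect_false(tr$qualifies[1])
  }
  # trace thresholds are consecutive steps from the start
  expect_equal(tr$threshold, seq(2.5, by = 0.1, length.out = nrow(tr)))

  co2 <- simulate_cohort(sim_scenario("lactate_threshold", n_patients = 1500),
                         seed = 74)
  res2 <- lactate_threshold_search(co2)
  tr2 <- res2$trace
  if (!is.na(res2$threshold)) {
    expect_equal(min(tr2$threshold[tr2$qualifies]), res2$threshold)
  }
  expect_equal(tr2$threshold, seq(3.0, by = -0.1, length.out = nrow(tr2)))
})

test_that("subgroup analysis returns stratum fits and an interaction p-value", {
  co <- small_sim(n = 800, seed = 75)
  res <- subgroup_analysis(co, "aki_flag")
  expect_equal(nrow(res$by_stratum), 2)
  expect_true(all(res$by_stratum$n > 0))
  expect_true(is.na(res$interaction_p) ||
                (res$interaction_p >= 0 && res$interaction_p <= 1))
  expect_error(subgroup_analysis(co, "not_a_column"),
               class = "albumsm_schema_error")
})

test_that("sensitivity exclusion removes flagged patients and their days", {
  co <- small_sim(n = 200, seed = 76)
  n_flagged <- sum(co$baselines$sbp_flag)
  out <- sensitivity_exclude(co, "sbp_flag")
  expect_equal(n_patients(out), 200 - n_flagged)
  expect_false(any(out$baselines$sbp_flag))
  expect_setequal(unique(out$days$patient_id), out$baselines$patient_id)

  # no flags set: identity
  co$baselines$sbp_flag <- FALSE
  expect_identical(sensitivity_exclude(co, "sbp_flag")$days, co$days)
  expect_error(sensitivity_exclude(co, "no_flag"), class = "albumsm_config_error")
})
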