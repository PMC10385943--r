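test_that("spec validation enforces numerator nesting", {
  expect_error(ipw_spec(denominator = ~ sofa, numerator = ~ map),
               class = "albumsm_config_error")
  s <- ipw_spec(denominator = ~ sofa + map, numerator = ~ sofa)
  expect_s3_class(s, "ipw_spec")
})

test_that("weights are the identity when numerator equals denominator", {
  co <- small_sim(n = 150, seed = 3)
  spec <- ipw_spec(denominator = ~ sofa + map, numerator = ~ sofa + map,
                   truncation = NULL)
  w <- suppressWarnings(stabilized_weights(co, spec))
  expect_equal(w$p_num, w$p_den, tolerance = 1e-10)
  expect_equal(w$sw_cum, rep(1, nrow(w)), tolerance = 1e-10)
})

test_that("cumulative weights are running products within patient", {
  co <- small_sim(n = 100, seed = 4)
  w <- suppressWarnings(stabilized_weights(co, ipw_spec(truncation = NULL)))
  by_pat <- split(w, w$patient_id)
  for (p in by_pat[1:10]) {
    expect_equal(p$sw_cum, cumprod(p$sw_day), tolerance = 1e-12)
  }
  expect_true(all(w$sw_cum > 0 & is.finite(w$sw_cum)))
  expect_true(all(w$p_num > 0 & w$p_num < 1))
  expect_true(all(w$p_den > 0 & w$p_den < 1))
})

test_that("treatment model recovers null and known coefficients", {
  # exposure independent of everything: non-intercept coefficients near 0
  p <- sim_scenario("no_confounding", n_patients = 1200)
  p$treat_coefs["prev_treat"] <- 0
  co <- simulate_cohort(p, seed = 8)
  # a design without the collinear albumin pair so slopes are well separated;
  # covariates differ in scale, so the null check is on the z statistic
  spec <- ipw_spec(denominator = ~ sofa + log(lactate) + map + vaso_nee +
                     serum_albumin)
  den <- fit_treatment_model(co, spec$denominator, spec)
  sm <- summary(den$model)$coefficients
  for (nm in c("sofa", "map", "serum_albumin", "prev_treat")) {
    row <- grep(nm, rownames(sm), value = TRUE)[1]
    expect_lt(abs(sm[row, "z value"]), 4)
  }

  # known logistic model: coefficient recovery
  co2 <- small_sim(n = 2500, seed = 9)
  den2 <- fit_treatment_model(co2, spec$denominator, spec)
  cf2 <- coef(den2$model)
  truth <- sim_truth(co2)$params$treat_coefs
  expect_lt(abs(cf2[["sofa"]] - truth[["sofa"]]), 0.05)
  expect_lt(abs(cf2[["log(lactate)"]] - truth[["log_lactate"]]), 0.2)
  expect_lt(abs(cf2[["prev_treat"]] - truth[["prev_treat"]]), 0.2)

  # degenerate single-row input
  one <- tiny_cohort()
  one$days <- one$days[1, ]
  one$baselines <- one$baselines[1, ]
  expect_error(fit_treatment_model(one, spec$denominator, spec),
               class = "albumsm_estimation_error")
})

test_that("per-day mean of cumulative stabilized weights stays near 1", {
  co <- small_sim(n = 1500, seed = 10)
  w <- suppressWarnings(stabilized_weights(co, ipw_spec(truncation = NULL)))
  d <- weight_diagnostics(w)
  tol <- 3 / sqrt(1500)
  for (t in 1:10) {
    expect_lt(abs(d$mean[d$day == t] - 1), tol)
  }
})

test_that("truncation winsorizes at type-1 percentiles and records bounds", {
  ws <- tibble::tibble(patient_id = c("a", "b", "c"), day = 1,
                       p_num = 0.5, p_den = 0.5, sw_day = 1,
                       sw_cum = c(1, 2, 100))
  ws <- albumsm:::new_weight_set(ws, ipw_spec())
  out <- truncate_weights(ws, 0, 200 / 3)
  expect_equal(out$sw_cum, c(1, 2, 2))
  expect_equal(unname(attr(out, "truncation_bounds")["upper"]), 2)

  # identity at (0, 100)
  id <- truncate_weights(ws, 0, 100)
  expect_equal(id$sw_cum, ws$sw_cum)

  # all-equal weights unchanged under any bounds
  eq <- ws; eq$sw_cum <- rep(1.3, 3)
  expect_equal(truncate_weights(eq, 10, 90)$sw_cum, rep(1.3, 3))
})

test_that("multinomial weights reduce to binary in the 2-level case", {
  co <- small_sim(n = 300, seed = 12)
  # collapse dose strata to none/any so K = 2
  co$days$dose_stratum <- factor(ifelse(co$days$treated, "any", "none"),
                                 levels = c("none", "any"))
  spec <- ipw_spec(truncation = NULL)
  wb <- suppressWarnings(stabilized_weights(co, spec))
  wm <- suppressWarnings(multinomial_weights(co, spec))
  expect_equal(wm$sw_cum, wb$sw_cum, tolerance = 1e-3)

  # uniform single-category: all weights 1
  co2 <- small_sim(n = 60, seed = 13)
  co2$days$treated <- FALSE
  co2$days$albumin_dose <- 0
  co2$days$dose_stratum <- dose_stratum(co2$days$albumin_dose)
  expect_warning(w1 <- stabilized_weights(co2, spec), "no variation")
  expect_equal(w1$sw_cum, rep(1, nrow(w1)))
  wm1 <- multinomial_weights(co2, spec)
  expect_equal(wm1$sw_cum, rep(1, nrow(wm1)))
})

test_that("five-stratum multinomial weights are positive, finite, mean near 1", {
  co <- small_sim(n = 800, seed = 14)
  w <- suppressWarnings(multinomial_weights(co, ipw_spec(truncation = NULL)))
  expect_true(all(is.finite(w$sw_cum) & w$sw_cum > 0))
  d <- weight_diagnostics(w)
  expect_lt(abs(d$mean[d$day == 3] - 1), 3 / sqrt(800))
})

test_that("enriching the numerator with confounders shrinks weight variance", {
  co <- small_sim(n = 500, seed = 15)
  base <- suppressWarnings(stabilized_weights(
    co, ipw_spec(truncation = NULL)))
  rich <- suppressWarnings(stabilized_weights(
    co, ipw_spec(numerator = ~ sofa + log(lactate) + map,
                 truncation = NULL)))
  expect_lt(var(log(rich$sw_cum)), var(log(base$sw_cum)))
})
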