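test_that("counting process construction conserves rows and events", {
  co <- tiny_cohort()
  rec <- build_counting_process(co)
  expect_equal(nrow(rec), 6)
  expect_equal(sum(rec$event), 1)
  expect_equal(rec$start, rec$stop - 1)

  # 3-day survivor: 3 records, no event; death on final interval carries event
  p1 <- rec[rec$patient_id == "p1", ]
  expect_equal(nrow(p1), 3)
  expect_true(p1$event[3])

  # weight alignment error when a person-day has no weight
  w <- suppressWarnings(stabilized_weights(co, ipw_spec(
    denominator = ~ sofa, truncation = NULL)))
  w2 <- w[-2, ]
  expect_error(build_counting_process(co, weights = w2),
               class = "albumsm_alignment_error")
})

test_that("fitted log-HR matches the brute-force partial likelihood oracle", {
  for (i in 1:25) {
    rec <- random_small_panel(sample(3:6, 1), seed = 400 + i)
    b_pkg <- suppressWarnings(fit_weighted_cox(rec)$coefficients[[1]])
    b_orc <- brute_cox_fit_1d(rec, "treated")
    expect_lt(abs(b_pkg - b_orc), 1e-8)
  }
  # also with non-unit weights: the weighted likelihood is maximized
  rec <- random_small_panel(6, seed = 990)
  rec$weight <- c(0.5, 1.5, 2, 1, 0.8, 1.2)[seq_len(nrow(rec))]
  b_pkg <- suppressWarnings(fit_weighted_cox(rec)$coefficients[[1]])
  expect_lt(abs(b_pkg - brute_cox_fit_1d(rec, "treated")), 1e-8)
})

test_that("integer weights equal row duplication exactly", {
  for (i in 1:10) {
    rec <- random_small_panel(6, seed = 700 + i)
    rec$weight <- sample(1:3, nrow(rec), replace = TRUE)
    dup <- rec[rep(seq_len(nrow(rec)), rec$weight), ]
    dup$weight <- 1
    b_w <- suppressWarnings(fit_weighted_cox(rec)$coefficients[[1]])
    b_d <- suppressWarnings(fit_weighted_cox(dup)$coefficients[[1]])
    expect_equal(b_w, b_d, tolerance = 1e-10)
  }
})

test_that("weight rescaling leaves the point estimate unchanged", {
  rec <- random_small_panel(6, seed = 55)
  rec$weight <- runif(nrow(rec), 0.5, 2)
  f1 <- suppressWarnings(fit_weighted_cox(rec))
  rec2 <- rec
  rec2$weight <- rec$weight * 2
  f2 <- suppressWarnings(fit_weighted_cox(rec2))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
})

test_that("degenerate inputs raise named estimation errors", {
  rec <- random_small_panel(5, seed = 1)
  rec$treated <- 1
  expect_error(fit_weighted_cox(rec), "no variation in exposure",
               class = "albumsm_estimation_error")
  rec2 <- random_small_panel(5, seed = 2)
  rec2$event <- FALSE
  expect_error(fit_weighted_cox(rec2), "zero events",
               class = "albumsm_estimation_error")
})

test_that("tidy and glance expose the fit in broom form", {
  co <- small_sim(n = 300, seed = 61)
  rec <- build_counting_process(co)
  fit <- fit_weighted_cox(rec)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "hr", "conf.low", "conf.high"))
  expect_equal(td$hr, exp(td$estimate))
  expect_true(td$conf.low < td$hr & td$hr < td$conf.high)
  gl <- glance(fit)
  expect_equal(gl$n_events, sum(rec$event))
  expect_equal(gl$minus2logl, -2 * gl$loglik)
  expect_true(gl$converged)
})

test_that("Heaviside periods partition follow-up and nest correctly", {
  co <- small_sim(n = 800, seed = 62)
  rec <- build_counting_process(co)
  hv <- heaviside_fit(rec)
  ph <- hv$period_hrs
  expect_equal(ph$days, c("1-7", "8-14", "15-21", "22-28"))
  expect_true(all(ph$hr[ph$estimable] > 0))

  # invalid cutpoints
  expect_error(heaviside_fit(rec, cutpoints = c(14, 7)),
               class = "albumsm_input_error")
  expect_error(heaviside_fit(rec, cutpoints = c(7, 40)),
               class = "albumsm_input_error")

  # single cutpoint with a homogeneous effect: both period HRs near overall
  overall <- fit_weighted_cox(rec)
  two <- heaviside_fit(rec, cutpoints = 14)
  expect_equal(nrow(two$period_hrs), 2)
  est <- two$period_hrs[two$period_hrs$estimable, ]
  for (k in seq_len(nrow(est))) {
    expect_true(est$conf.low[k] < tidy(overall)$hr[1],
                info = "weekly CI overlaps the overall HR")
    expect_true(est$conf.high[k] > tidy(overall)$hr[1] * 0.8)
  }

  # no events after day 7 -> later periods non-estimable
  early <- rec[rec$stop <= 7, ]
  hv2 <- heaviside_fit(early, cutpoints = c(3, 5))
  expect_true(hv2$period_hrs$estimable[1])
})

test_that("extended time-varying Cox equals the weighted engine at unit weights", {
  co <- small_sim(n = 400, seed = 63)
  rec <- build_counting_process(co, covariates = c("sofa", "map"))
  a <- extended_cox_timevarying(rec, covariates = c("sofa", "map"))
  rec$weight <- 1
  b <- fit_weighted_cox(rec, terms = c("treated", "sofa", "map"))
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-10)
})

test_that("collinearity filter drops the lower-priority member of tight pairs", {
  set.seed(77)
  d <- tibble::tibble(a = rnorm(200))
  d$b <- d$a                          # identical copy
  d$c <- rnorm(200)                   # independent
  d$e <- 0.9 * d$c + sqrt(1 - 0.81) * rnorm(200)
  out <- collinearity_filter(d, c("a", "b", "c", "e"), r_threshold = 0.8)
  expect_true("a" %in% out$retained)
  expect_false("b" %in% out$retained)
  expect_true("c" %in% out$retained)

  # orthogonal columns all retained
  d2 <- tibble::tibble(x = rnorm(100), y = rnorm(100))
  expect_equal(collinearity_filter(d2, c("x", "y"))$retained, c("x", "y"))

  # r just below the threshold: both retained
  n <- 4000
  base <- rnorm(n)
  d3 <- tibble::tibble(u = base, v = 0.79 * base + sqrt(1 - 0.79^2) * rnorm(n))
  r <- cor(d3$u, d3$v)
  res <- collinearity_filter(d3, c("u", "v"), r_threshold = max(r + 0.01, 0.8))
  expect_equal(res$retained, c("u", "v"))
})

test_that("stepwise selection finds prognostic covariates, trace non-increasing", {
  set.seed(88)
  co <- small_sim(n = 700, seed = 88)
  rec <- build_counting_process(co, covariates = c("sofa"))
  # sofa is strongly prognostic in the generator; add pure-noise candidates
  for (k in 1:3) rec[[paste0("noise", k)]] <- rnorm(nrow(rec))
  sel <- stepwise_select(rec, candidates = c("sofa", paste0("noise", 1:3)))
  expect_true("sofa" %in% sel$selected)
  expect_true(all(diff(sel$trace$minus2logl) <= 0))

  # empty candidate list: exposure-only model
  sel0 <- stepwise_select(rec, candidates = character())
  expect_equal(sel0$selected, character())
  expect_equal(names(sel0$fit$coefficients), "treatedTRUE")
})
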