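#' Indication rule for albumin initiation
#'
#' An interval condition on a clinical parameter measured on the day of the
#' first albumin infusion. Prespecified families mirror common bedside
#' triggers: five serum-albumin bins (closed-left/open-right except the
#' extremes), lactate at or above a bound, MAP below a bound, and an NEE
#' dose band closed at both ends.
#'
#' @param variable One of `"serum_albumin"`, `"lactate"`, `"map"`,
#'   `"vaso_nee"`.
#' @param lower,upper Interval bounds (use `-Inf`/`Inf` for one-sided rules).
#' @param closed_lower,closed_upper Whether each bound is included.
#' @return An `indication_rule`.
#' @export
indication_rule <- function(variable, lower = -Inf, upper = Inf,
                            closed_lower = TRUE, closed_upper = FALSE) {
  variable <- match.arg(variable, c("serum_albumin", "lactate", "map", "vaso_nee"))
  if (!(lower < upper)) abort("rule interval requires lower < upper",
                              class = "albumsm_input_error")
  structure(list(variable = variable, lower = lower, upper = upper,
                 closed_lower = closed_lower, closed_upper = closed_upper),
            class = "indication_rule")
}

#' @export
format.indication_rule <- function(x, ...) {
  paste0(x$variable, " in ", if (x$closed_lower) "[" else "(", x$lower, ", ",
         x$upper, if (x$closed_upper) "]" else ")")
}

#' @export
print.indication_rule <- function(x, ...) {
  cat("<indication_rule>", format(x), "\n")
  invisible(x)
}

rule_matches <- function(rule, value) {
  lo <- if (rule$closed_lower) value >= rule$lower else value > rule$lower
  hi <- if (rule$closed_upper) value <= rule$upper else value < rule$upper
  lo & hi & !is.na(value)
}

#' Prespecified serum-albumin indication bins
#'
#' The five bins `< 2.5`, `[2.5, 3.0)`, `[3.0, 3.5)`, `[3.5, 4.0)` and
#' `>= 4.0` g/dL; their treated arms partition the treated patients with a
#' non-missing first-infusion-day albumin.
#' @return List of `indication_rule`s.
#' @export
albumin_indication_bins <- function() {
  list(
    indication_rule("serum_albumin", -Inf, 2.5),
    indication_rule("serum_albumin", 2.5, 3.0),
    indication_rule("serum_albumin", 3.0, 3.5),
    indication_rule("serum_albumin", 3.5, 4.0),
    indication_rule("serum_albumin", 4.0, Inf, closed_upper = TRUE)
  )
}

#' Build an indication-defined sub-cohort
#'
#' The treated arm is every patient whose value of the rule variable on the
#' day of their first albumin infusion lies in the rule interval; the
#' comparator arm is every never-treated patient (identical across all
#' sub-cohorts of a cohort). Treated patients failing the rule are removed
#' from the treated arm, but their *pre-initiation* person-days are retained
#' and they are administratively censored on the day of their (off-rule)
#' first infusion. Deleting their whole history instead would condition the
#' untreated risk set on a future event — which treatment they eventually
#' initiated — and biases the weighted contrast even under a null effect;
#' censoring at deviation keeps the person-time selection depend only on the
#' past. Follow-up for both arms runs from ICU day 1.
#'
#' @param cohort An `icu_cohort`.
#' @param rule An [indication_rule()].
#' @return An `icu_cohort` containing the two arms plus the censored
#'   pre-initiation person-time, with `meta$indication` carrying the rule,
#'   the arm ids (`treated_ids`, `comparator_ids`) and sizes;
#'   `meta$estimable` is `FALSE` (with a warning) when the treated arm is
#'   empty.
#' @export
build_subcohort <- function(cohort, rule) {
  os <- outcome_summary(cohort)
  first_day <- os[!is.na(os$first_treated_day),
                  c("patient_id", "first_treated_day")]
  vals <- dplyr::left_join(
    first_day,
    cohort$days[c("patient_id", "day", rule$variable)],
    by = c("patient_id", "first_treated_day" = "day")
  )
  in_rule <- rule_matches(rule, vals[[rule$variable]])
  treated_ids <- vals$patient_id[in_rule]
  off_rule <- vals$patient_id[!in_rule]
  comparator_ids <- os$patient_id[!os$ever_treated]
  cut <- setNames(vals$first_treated_day, vals$patient_id)
  days <- dplyr::filter(cohort$days,
                        !(.data$patient_id %in% off_rule) |
                          .data$day < cut[.data$patient_id])
  keep <- unique(days$patient_id)
  sub <- cohort
  sub$baselines <- dplyr::filter(cohort$baselines, .data$patient_id %in% keep)
  sub$days <- days
  estimable <- length(treated_ids) > 0
  if (!estimable) warn(paste0("empty treated arm for rule ", format(rule)))
  sub$meta$indication <- list(rule = rule,
                              treated_ids = treated_ids,
                              comparator_ids = comparator_ids,
                              n_treated = length(treated_ids),
                              n_comparator = length(comparator_ids),
                              n_censored_contributors =
                                sum(off_rule %in% keep))
  sub$meta$estimable <- estimable
  sub
}

#' Fit the marginal structural Cox model within a sub-cohort
#'
#' Runs the full weighting and weighted-Cox pipeline inside the sub-cohort:
#' stabilized weights are re-estimated on the sub-cohort panel, then the
#' exposure-only weighted Cox model is fitted. With `n_family > 1` a
#' Bonferroni-adjusted significance flag across the rule family is added.
#'
#' @param subcohort Output of [build_subcohort()].
#' @param spec An [ipw_spec()].
#' @param n_family Size of the prespecified rule family for the Bonferroni
#'   adjustment (e.g. 5 for the albumin bins).
#' @param alpha Family significance level (default 0.05).
#' @return An `mscm_fit` with an `indication` element (rule, arm sizes,
#'   adjusted-significance flag), or `NULL` with a warning when the
#'   sub-cohort is non-estimable.
#' @export
evaluate_indication <- function(subcohort, spec = ipw_spec(), n_family = 1,
                                alpha = 0.05) {
  if (isFALSE(subcohort$meta$estimable)) {
    warn("sub-cohort non-estimable (empty treated arm)")
    return(NULL)
  }
  w <- stabilized_weights(subcohort, spec)
  rec <- build_counting_process(subcohort, weights = w)
  n_exposed_events <- sum(rec$event & rec$treated)
  if (n_exposed_events == 0) {
    warn("sub-cohort non-estimable (no exposed events)")
    return(NULL)
  }
  fit <- fit_weighted_cox(rec)
  td <- tidy(fit)
  fit$indication <- c(subcohort$meta$indication,
                      list(p_adjusted_significant =
                             td$p.value[td$term == "treatedTRUE" | td$term == "treated"][1] <
                             alpha / n_family))
  fit
}

threshold_search <- function(cohort, thresholds, make_rule, spec, min_treated) {
  trace <- tibble::tibble(threshold = numeric(), hr = numeric(),
                          conf.low = numeric(), conf.high = numeric(),
                          n_treated = integer(), qualifies = logical())
  last_ok <- NA_real_
  for (cth in thresholds) {
    sub <- suppressWarnings(build_subcohort(cohort, make_rule(cth)))
    fit <- if (isTRUE(sub$meta$estimable) &&
               sub$meta$indication$n_treated >= min_treated) {
      tryCatch(suppressWarnings(evaluate_indication(sub, spec)),
               error = function(e) NULL)
    } else NULL
    if (is.null(fit)) {
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        threshold = cth, hr = NA_real_, conf.low = NA_real_,
        conf.high = NA_real_, n_treated = sub$meta$indication$n_treated,
        qualifies = FALSE))
      break
    }
    td <- tidy(fit)[1, ]
    ok <- td$conf.high < 1
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      threshold = cth, hr = td$hr, conf.low = td$conf.low,
      conf.high = td$conf.high, n_treated = sub$meta$indication$n_treated,
      qualifies = ok))
    if (!ok) break
    last_ok <- cth
  }
  list(threshold = last_ok, trace = trace)
}

#' Data-driven serum-albumin trigger for albumin initiation
#'
#' Iterates rules of the form "first-infusion-day serum albumin `< c`",
#' raising `c` by `step` from `start`, and fits the sub-cohort marginal
#' structural model at each threshold. The search proceeds while the upper
#' 95\% confidence bound of the hazard ratio stays below 1 and stops at the
#' first threshold where the association is lost; the returned trigger is
#' the highest qualifying threshold (`NA` if none qualifies, including the
#' first).
#'
#' @param cohort An `icu_cohort`.
#' @param start First threshold in g/dL (default 2.5).
#' @param stop Last threshold to consider (default 4.0).
#' @param step Increment in g/dL (default 0.1).
#' @param spec An [ipw_spec()].
#' @param min_treated Minimum treated-arm size for a threshold to be
#'   evaluable.
#' @return List with `threshold` (g/dL or `NA`) and the search `trace`.
#' @export
albumin_threshold_search <- function(cohort, start = 2.5, stop = 4.0,
                                     step = 0.1, spec = ipw_spec(),
                                     min_treated = 10) {
  stopifnot(step > 0)
  thresholds <- seq(start, stop, by = step)
  threshold_search(cohort, thresholds,
                   function(cth) indication_rule("serum_albumin", -Inf, cth),
                   spec, min_treated)
}

#' Data-driven lactate trigger for albumin initiation
#'
#' Mirrors [albumin_threshold_search()] downward: rules of the form
#' "first-infusion-day lactate `>= c`", lowering `c` by `step` from `start`.
#' "Consistently associated" is read strictly: every threshold from `start`
#' down to the returned value must qualify, and a single failing
#' intermediate stops the search.
#'
#' @param cohort An `icu_cohort`.
#' @param start First threshold in mmol/L (default 3.0).
#' @param floor Lowest threshold to consider (default 1.0).
#' @param step Decrement in mmol/L (default 0.1).
#' @param spec An [ipw_spec()].
#' @param min_treated Minimum treated-arm size.
#' @return List with `threshold` (mmol/L or `NA`) and the search `trace`.
#' @export
lactate_threshold_search <- function(cohort, start = 3.0, floor = 1.0,
                                     step = 0.1, spec = ipw_spec(),
                                     min_treated = 10) {
  stopifnot(step > 0)
  thresholds <- seq(start, floor, by = -step)
  threshold_search(cohort, thresholds,
                   function(cth) indication_rule("lactate", cth, Inf,
                                                 closed_lower = TRUE),
                   spec, min_treated)
}

#' Subgroup analyses with interaction tests
#'
#' Fits the weighted Cox model within each level of a baseline subgroup
#' variable (weights re-estimated per stratum) and tests effect
#' heterogeneity by the robust Wald test of the exposure-by-subgroup product
#' term in the pooled weighted model.
#'
#' @param cohort An `icu_cohort`.
#' @param subgroup_var Name of a baseline column with two or more levels
#'   (logical or factor).
#' @param spec An [ipw_spec()].
#' @param min_events Strata with fewer events are flagged non-estimable.
#' @return List with `by_stratum` (tibble: level, n, events, hr, CI) and
#'   `interaction_p`.
#' @export
subgroup_analysis <- function(cohort, subgroup_var, spec = ipw_spec(),
                              min_events = 2) {
  b <- cohort$baselines
  if (!subgroup_var %in% names(b)) {
    abort(paste0("schema error: no baseline column '", subgroup_var, "'"),
          class = "albumsm_schema_error")
  }
  g <- factor(b[[subgroup_var]])
  rows <- purrr::map(levels(g), function(lev) {
    ids <- b$patient_id[g == lev]
    sub <- cohort
    sub$baselines <- b[g == lev, , drop = FALSE]
    sub$days <- dplyr::filter(cohort$days, .data$patient_id %in% ids)
    n_ev <- sum(sub$days$event)
    if (n_ev < min_events || length(unique(sub$days$treated)) < 2) {
      return(tibble::tibble(level = lev, n = length(ids), events = n_ev,
                            hr = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_, estimable = FALSE))
    }
    w <- suppressWarnings(stabilized_weights(sub, spec))
    fit <- fit_weighted_cox(build_counting_process(sub, weights = w))
    td <- tidy(fit)[1, ]
    tibble::tibble(level = lev, n = length(ids), events = n_ev,
                   hr = td$hr, conf.low = td$conf.low, conf.high = td$conf.high,
                   estimable = TRUE)
  })
  # pooled model with product term for the interaction test
  w_all <- suppressWarnings(stabilized_weights(cohort, spec))
  rec <- build_counting_process(cohort, weights = w_all)
  rec$subgroup <- as.integer(factor(
    b[[subgroup_var]][match(rec$patient_id, b$patient_id)])) - 1L
  rec$tx <- as.integer(rec$treated)
  rec$tx_x_subgroup <- rec$tx * rec$subgroup
  p_int <- NA_real_
  fit_int <- tryCatch(
    fit_weighted_cox(rec, terms = c("tx", "subgroup", "tx_x_subgroup"),
                     exposure = "tx"),
    error = function(e) NULL)
  if (!is.null(fit_int)) {
    td <- tidy(fit_int)
    p_int <- td$p.value[td$term == "tx_x_subgroup"]
  }
  list(by_stratum = dplyr::bind_rows(rows), interaction_p = p_int)
}

#' Exclude patients carrying a baseline flag
#'
#' Sensitivity-analysis helper: removes flagged patients (e.g. spontaneous
#' bacterial peritonitis) and their person-days; the downstream pipeline is
#' unchanged.
#'
#' @param cohort An `icu_cohort`.
#' @param flag Name of a logical baseline column.
#' @return The reduced `icu_cohort`.
#' @export
sensitivity_exclude <- function(cohort, flag) {
  if (!flag %in% names(cohort$baselines)) {
    abort(paste0("configuration error: no baseline flag '", flag, "'"),
          class = "albumsm_config_error")
  }
  keep <- cohort$baselines$patient_id[!cohort$baselines[[flag]]]
  cohort$baselines <- dplyr::filter(cohort$baselines, .data$patient_id %in% keep)
  cohort$days <- dplyr::filter(cohort$days, .data$patient_id %in% keep)
  cohort
}
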