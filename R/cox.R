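#' Build the counting-process panel for weighted Cox fitting
#'
#' Converts the person-day panel into one `(start, stop]` record per at-risk
#' person-day, carrying the day's exposure, covariates, stabilized weight and
#' the event indicator for that day's risk interval. Day `t` covers the
#' interval `(t-1, t]` on the analysis clock; under the package's one-day-lag
#' convention the day's covariates and treatment predict the event of the
#' following calendar interval, and relabelling event times this way leaves
#' the partial likelihood unchanged.
#'
#' @param cohort An `icu_cohort`.
#' @param weights Optional `weight_set` from [stabilized_weights()]; unit
#'   weights when `NULL`.
#' @param covariates Character vector of additional columns (day-level or
#'   baseline) to carry into the records.
#' @param exposure Exposure column name, default `"treated"`.
#' @return Tibble of survival records: `patient_id`, `start`, `stop`,
#'   exposure, covariates, `weight`, `event`.
#' @export
build_counting_process <- function(cohort, weights = NULL, covariates = NULL,
                                   exposure = "treated") {
  panel <- as_tibble(cohort)
  keep <- c("patient_id", "day", exposure, covariates, "event")
  miss <- setdiff(keep, names(panel))
  if (length(miss) > 0) {
    abort(paste0("schema error: missing column(s): ", paste(miss, collapse = ", ")),
          class = "albumsm_schema_error")
  }
  rec <- panel[keep]
  if (is.null(weights)) {
    rec$weight <- 1
  } else {
    w <- tibble::as_tibble(weights)[c("patient_id", "day", "sw_cum")]
    rec <- dplyr::left_join(rec, w, by = c("patient_id", "day"))
    if (anyNA(rec$sw_cum)) {
      abort("alignment error: weight missing for at-risk person-day(s)",
            class = "albumsm_alignment_error")
    }
    rec$weight <- rec$sw_cum
    rec$sw_cum <- NULL
  }
  rec$start <- rec$day - 1
  rec$stop <- rec$day
  rec$day <- NULL
  dplyr::relocate(rec, "patient_id", "start", "stop")
}

#' Fit a weighted Cox proportional-hazards model
#'
#' Maximizes the weight-incorporated partial likelihood (weights multiply
#' each subject's contribution to the event terms and the risk-set sums) on
#' counting-process records, with Breslow tie handling by default and a
#' robust sandwich variance clustered on patient — required because the
#' weights make the model likelihood a pseudo-likelihood. This is the engine
#' behind the marginal structural Cox model, the Heaviside period fits and
#' the unweighted extended time-varying Cox model.
#'
#' @param records Counting-process tibble from [build_counting_process()].
#' @param terms Character vector of model terms; defaults to the exposure
#'   column alone.
#' @param exposure Name of the exposure column (checked for variation).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An `mscm_fit` object; see [tidy.mscm_fit()] and
#'   [glance.mscm_fit()].
#' @export
fit_weighted_cox <- function(records, terms = NULL, exposure = "treated",
                             ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (is.null(terms)) terms <- exposure
  if (sum(records$event) < 1) {
    abort("estimation error: zero events", class = "albumsm_estimation_error")
  }
  if (exposure %in% terms && length(unique(records[[exposure]])) == 1) {
    abort("estimation error: no variation in exposure", class = "albumsm_estimation_error")
  }
  f <- as.formula(paste("survival::Surv(start, stop, event) ~",
                        paste(terms, collapse = " + "),
                        "+ survival::cluster(patient_id)"))
  fit <- survival::coxph(f, data = records, weights = records$weight,
                         ties = ties, control = survival::coxph.control(
                           eps = 1e-12, toler.chol = 1e-13, iter.max = 50))
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15)) {
    culprit <- names(coef(fit))[which.max(abs(coef(fit)))]
    abort(paste0("estimation error: monotone likelihood / separation on term '",
                 culprit, "'"),
          class = "albumsm_estimation_error")
  }
  new_mscm_fit(fit, records, terms = terms, exposure = exposure, ties = ties)
}

new_mscm_fit <- function(fit, records, terms, exposure, ties, period_hrs = NULL) {
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))  # robust when cluster() present
  structure(
    list(
      coefficients = beta,
      hr = exp(beta),
      se_robust = se,
      conf_low = exp(beta - qnorm(0.975) * se),
      conf_high = exp(beta + qnorm(0.975) * se),
      robust_vcov = vcov(fit),
      loglik = fit$loglik[length(fit$loglik)],
      minus2logl = -2 * fit$loglik[length(fit$loglik)],
      n_events = fit$nevent,
      n_patients = length(unique(records$patient_id)),
      n_records = nrow(records),
      converged = all(is.finite(coef(fit))) && fit$iter < 50,
      exposure = exposure,
      terms = terms,
      ties = ties,
      period_hrs = period_hrs,
      model = fit
    ),
    class = "mscm_fit"
  )
}

#' @export
print.mscm_fit <- function(x, ...) {
  cat("<mscm_fit> weighted Cox model, ", x$n_events, " events / ",
      x$n_patients, " patients (", x$ties, " ties)\n", sep = "")
  td <- tidy(x)
  print(as.data.frame(td[, c("term", "hr", "conf.low", "conf.high", "p.value")]),
        row.names = FALSE, digits = 3)
  if (!is.null(x$period_hrs)) {
    cat("period-specific hazard ratios:\n")
    print(as.data.frame(x$period_hrs), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Tidy a weighted Cox fit
#'
#' @param x An `mscm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate` (log HR),
#'   `std.error` (robust), `statistic`, `p.value`, `hr`, `conf.low`,
#'   `conf.high` (95\%, on the HR scale).
#' @method tidy mscm_fit
#' @export
tidy.mscm_fit <- function(x, ...) {
  z <- x$coefficients / x$se_robust
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se_robust),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    hr = unname(x$hr),
    conf.low = unname(x$conf_low),
    conf.high = unname(x$conf_high)
  )
}

#' @rdname tidy.mscm_fit
#' @return `glance()`: one-row tibble with `n_patients`, `n_records`,
#'   `n_events`, `loglik`, `minus2logl`, `converged`.
#' @method glance mscm_fit
#' @export
glance.mscm_fit <- function(x, ...) {
  tibble::tibble(n_patients = x$n_patients, n_records = x$n_records,
                 n_events = x$n_events, loglik = x$loglik,
                 minus2logl = x$minus2logl, converged = x$converged)
}

#' Period-specific hazard ratios via Heaviside step functions
#'
#' Interacts the exposure with indicators of consecutive follow-up periods
#' (weeks 1-4 by default), so each period gets its own hazard ratio while
#' sharing the confounder adjustment. Periods with no exposed events are
#' reported as non-estimable (`NA` with `estimable = FALSE`).
#'
#' @param records Counting-process tibble.
#' @param cutpoints Increasing interior cutpoints in days (default
#'   `c(7, 14, 21)` for four weeks of a 28-day horizon).
#' @param terms Additional adjustment terms.
#' @param exposure Exposure column.
#' @param ties Tie method.
#' @return An `mscm_fit` with a `period_hrs` tibble (`period`, `days`, `hr`,
#'   `conf.low`, `conf.high`, `estimable`).
#' @export
heaviside_fit <- function(records, cutpoints = c(7, 14, 21), terms = NULL,
                          exposure = "treated", ties = "breslow") {
  horizon <- max(records$stop)
  if (any(diff(cutpoints) <= 0) || any(cutpoints <= 0) || any(cutpoints >= horizon)) {
    abort("input error: cutpoints must be strictly increasing within (0, horizon)",
          class = "albumsm_input_error")
  }
  breaks <- c(0, cutpoints, horizon)
  split <- survival::survSplit(
    as.formula("Surv(start, stop, event) ~ .", env = asNamespace("survival")),
    data = as.data.frame(records), cut = cutpoints, episode = "period_id")
  split$period_id <- findInterval(split$start, breaks, left.open = FALSE,
                                  rightmost.closed = TRUE) |>
    pmin(length(breaks) - 1)
  n_periods <- length(breaks) - 1
  labels <- paste0("period", seq_len(n_periods))
  for (k in seq_len(n_periods)) {
    split[[paste0(exposure, "_", labels[k])]] <-
      as.integer(split[[exposure]]) * as.integer(split$period_id == k)
  }
  # estimability: a period needs events under both exposure levels, and a
  # period whose likelihood is still monotone is dropped and flagged
  est <- vapply(seq_len(n_periods), function(k) {
    in_k <- split$period_id == k
    sum(split$event[in_k & split[[exposure]] > 0]) > 0 &&
      sum(split$event[in_k & split[[exposure]] == 0]) > 0
  }, logical(1))
  fit <- NULL
  while (is.null(fit)) {
    if (!any(est)) {
      abort("estimation error: no estimable exposure period",
            class = "albumsm_estimation_error")
    }
    use_terms <- c(paste0(exposure, "_", labels[est]), terms)
    fit <- tryCatch(
      fit_weighted_cox(tibble::as_tibble(split), terms = use_terms,
                       exposure = paste0(exposure, "_", labels[which(est)[1]]),
                       ties = ties),
      albumsm_estimation_error = function(e) {
        hit <- regmatches(conditionMessage(e),
                          regexpr(paste0(exposure, "_period[0-9]+"),
                                  conditionMessage(e)))
        if (length(hit) == 1) {
          k <- as.integer(sub(paste0(exposure, "_period"), "", hit))
          est[k] <<- FALSE
          warn(paste0("period ", k, " non-estimable (monotone likelihood)"))
          NULL
        } else {
          stop(e)
        }
      })
  }
  ph <- tibble::tibble(
    period = labels,
    days = paste0(breaks[-length(breaks)] + 1, "-", breaks[-1]),
    hr = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
    estimable = est
  )
  td <- tidy(fit)
  for (k in which(est)) {
    row <- td[td$term == paste0(exposure, "_", labels[k]), ]
    ph$hr[k] <- row$hr
    ph$conf.low[k] <- row$conf.low
    ph$conf.high[k] <- row$conf.high
  }
  fit$period_hrs <- ph
  fit
}

#' Unweighted extended Cox model with time-varying confounders
#'
#' The robustness companion to the weighted analysis: the same
#' counting-process engine with unit weights, adjusting directly for the
#' time-varying confounders instead of weighting them away. Valid only in
#' the absence of treatment-confounder feedback, which is why it serves as a
#' sensitivity rather than the primary estimator.
#'
#' @param records Counting-process tibble (weights are ignored).
#' @param covariates Character vector of adjustment columns.
#' @param exposure Exposure column.
#' @param ties Tie method.
#' @return An `mscm_fit`.
#' @export
extended_cox_timevarying <- function(records, covariates, exposure = "treated",
                                     ties = "breslow") {
  records$weight <- 1
  fit_weighted_cox(records, terms = c(exposure, covariates),
                   exposure = exposure, ties = ties)
}
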