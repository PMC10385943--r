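#' Specification of the daily treatment-probability models
#'
#' Declares the numerator and denominator models of the stabilized inverse
#' probability of treatment weight. Both models are pooled over days and are
#' automatically augmented with treatment history (`prev_treat`, up to
#' `history_order` lags) and a restricted cubic spline in the ICU day, so the
#' formulas carry only the covariates. The numerator conditions on history
#' and time alone by default, so the weighted exposure-only Cox model
#' estimates a marginal effect; covariates added to the numerator must also
#' be adjusted for in the outcome model.
#'
#' @param denominator One-sided formula of baseline plus time-varying
#'   confounders. The default follows the confounder set used throughout the
#'   package: baseline age, gender, admission type, ethnicity, infection
#'   site and serum albumin, plus daily SOFA, log lactate, MAP, vasopressor
#'   dose, urine output, P/F ratio and serum albumin.
#' @param numerator One-sided formula of covariates for the numerator model
#'   (default `~ 1`); every numerator term must also appear in the
#'   denominator.
#' @param history_order Number of lagged daily-treatment indicators included
#'   in both models (default 1; 0 drops history).
#' @param day_spline_df Degrees of freedom of the natural spline in `day`
#'   (default 3); reduced automatically when the panel has few distinct days.
#' @param link `"logistic"` for the binary any-dose exposure,
#'   `"multinomial"` for the five dose strata.
#' @param truncation Percentile bounds for weight truncation as
#'   `c(lower, upper)`, or `NULL` to disable (default `c(1, 99)`).
#' @return An `ipw_spec` list.
#' @export
ipw_spec <- function(denominator = ~ sofa + log(lactate) + map + vaso_nee +
                       log1p(urine_output) + pf_ratio + serum_albumin +
                       age + gender + admission_type + ethnicity +
                       infection_site + baseline_albumin,
                     numerator = ~ 1,
                     history_order = 1,
                     day_spline_df = 3,
                     link = c("logistic", "multinomial"),
                     truncation = c(1, 99)) {
  link <- match.arg(link)
  num_terms <- attr(terms(numerator), "term.labels")
  den_terms <- attr(terms(denominator), "term.labels")
  extra <- setdiff(num_terms, den_terms)
  if (length(extra) > 0) {
    abort(paste0("numerator terms must be a subset of denominator terms; not found: ",
                 paste(extra, collapse = ", ")),
          class = "albumsm_config_error")
  }
  if (history_order < 0) abort("history_order must be >= 0", class = "albumsm_config_error")
  structure(list(denominator = denominator, numerator = numerator,
                 history_order = history_order, day_spline_df = day_spline_df,
                 link = link, truncation = truncation),
            class = "ipw_spec")
}

# panel with lagged treatment indicators
panel_with_history <- function(cohort, history_order = 1) {
  panel <- as_tibble(cohort)
  panel <- dplyr::group_by(panel, .data$patient_id)
  for (k in seq_len(max(history_order, 1))) {
    panel <- dplyr::mutate(panel,
                           !!paste0("prev_treat", ifelse(k == 1, "", k)) :=
                             dplyr::lag(as.integer(.data$treated), n = k, default = 0L))
  }
  dplyr::ungroup(panel)
}

history_terms <- function(history_order) {
  if (history_order == 0) return(character())
  paste0("prev_treat", c("", if (history_order > 1) 2:history_order))
}

day_term <- function(panel, df) {
  nd <- length(unique(panel$day))
  df_eff <- min(df, nd - 1)
  if (df_eff < 1) return(character())
  paste0("splines::ns(day, df = ", df_eff, ")")
}

build_model_formula <- function(response, covariate_formula, panel, spec) {
  rhs <- c(attr(terms(covariate_formula), "term.labels"),
           history_terms(spec$history_order),
           day_term(panel, spec$day_spline_df))
  if (length(rhs) == 0) rhs <- "1"
  as.formula(paste(response, "~", paste(rhs, collapse = " + ")),
             env = environment())
}

clamp_prob <- function(p, bound = 1e-6, label = "treatment") {
  n_clamped <- sum(p < bound | p > 1 - bound, na.rm = TRUE)
  if (n_clamped > 0) {
    warn(paste0(n_clamped, " fitted ", label,
                " probabilities clamped to [1e-06, 1 - 1e-06];",
                " possible positivity violation"))
  }
  pmin(pmax(p, bound), 1 - bound)
}

#' Fit a pooled daily treatment-probability model
#'
#' Maximum-likelihood logistic (or multinomial) regression of the observed
#' daily exposure on the given covariates, treatment history and a spline in
#' the ICU day, pooled over all at-risk person-days.
#'
#' @param cohort An `icu_cohort`.
#' @param covariates One-sided formula of covariates.
#' @param spec An [ipw_spec()] (supplies history order, day spline and link).
#' @param response Exposure column: `"treated"` or `"dose_stratum"`.
#' @return List with the fitted `model`, the model `formula`, and `p_obs`,
#'   the fitted probability of each row's observed exposure.
#' @export
fit_treatment_model <- function(cohort, covariates, spec = ipw_spec(),
                                response = c("treated", "dose_stratum")) {
  response <- match.arg(response)
  panel <- panel_with_history(cohort, spec$history_order)
  if (nrow(panel) < 2) {
    abort("estimation error: insufficient data (need at least 2 person-day rows)",
          class = "albumsm_estimation_error")
  }
  f <- build_model_formula(response, covariates, panel, spec)
  if (response == "treated") {
    fit <- glm(f, data = panel, family = binomial())
    if (!fit$converged) {
      abort(paste0("estimation error: treatment model failed to converge",
                   " (max |score| ", format(max(abs(colSums(
                     model.matrix(fit) * (panel$treated - fit$fitted.values))))),
                   ")"),
            class = "albumsm_estimation_error")
    }
    phat <- clamp_prob(fit$fitted.values)
    p_obs <- ifelse(panel$treated, phat, 1 - phat)
  } else {
    y <- droplevels(factor(panel$dose_stratum))
    if (nlevels(y) < 2) {
      return(list(model = NULL, formula = f, p_obs = rep(1, nrow(panel)),
                  single_level = TRUE))
    }
    if (nlevels(factor(panel$dose_stratum)) > nlevels(y)) {
      warn("dose strata with zero occurrences dropped from the multinomial model")
    }
    panel$.y <- y
    f <- update(f, .y ~ .)
    fit <- nnet::multinom(f, data = panel, trace = FALSE, maxit = 300)
    pr <- predict(fit, newdata = panel, type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-level case
    p_obs <- clamp_prob(pr[cbind(seq_len(nrow(panel)), as.integer(y))])
  }
  list(model = fit, formula = f, p_obs = p_obs)
}

#' Cumulative stabilized inverse-probability-of-treatment weights
#'
#' For each person-day, the stabilized weight is the ratio of the numerator
#' probability of the observed exposure (given history and time) to the
#' denominator probability (given additionally the confounders), accumulated
#' as a running product within patient. Both probabilities are retained as
#' an audit trail.
#'
#' @param cohort An `icu_cohort`.
#' @param spec An [ipw_spec()].
#' @return A `weight_set` tibble: `patient_id`, `day`, `p_num`, `p_den`,
#'   `sw_day`, `sw_cum`, with truncation applied when the spec requests it.
#' @examples
#' co <- simulate_cohort(sim_params(n_patients = 120), seed = 3)
#' w <- stabilized_weights(co)
#' summary(w$sw_cum)
#' @export
stabilized_weights <- function(cohort, spec = ipw_spec()) {
  panel <- panel_with_history(cohort, spec$history_order)
  response <- if (spec$link == "logistic") "treated" else "dose_stratum"
  if (response == "treated" && length(unique(panel$treated)) == 1) {
    warn("no variation in exposure; all stabilized weights set to 1")
    ws <- tibble::tibble(patient_id = panel$patient_id, day = panel$day,
                         p_num = 1, p_den = 1, sw_day = 1, sw_cum = 1)
    return(new_weight_set(ws, spec, truncation_bounds = NULL))
  }
  den <- fit_treatment_model(cohort, spec$denominator, spec, response)
  num <- fit_treatment_model(cohort, spec$numerator, spec, response)
  # exactly 1 is legitimate for a degenerate single-category exposure
  if (any(den$p_obs <= 0 | den$p_obs > 1) || any(num$p_obs <= 0 | num$p_obs > 1)) {
    abort("probability outside (0, 1) after clamping", class = "albumsm_estimation_error")
  }
  ws <- tibble::tibble(patient_id = panel$patient_id, day = panel$day,
                       p_num = num$p_obs, p_den = den$p_obs) |>
    dplyr::mutate(sw_day = .data$p_num / .data$p_den) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(sw_cum = cumprod(.data$sw_day)) |>
    dplyr::ungroup()
  out <- new_weight_set(ws, spec, truncation_bounds = NULL,
                        models = list(numerator = num$formula,
                                      denominator = den$formula))
  if (!is.null(spec$truncation)) {
    out <- truncate_weights(out, spec$truncation[1], spec$truncation[2])
  }
  out
}

#' @rdname stabilized_weights
#' @details `multinomial_weights()` is the five-stratum analogue: the
#'   probability of the observed dose stratum replaces the probability of the
#'   binary exposure in numerator and denominator.
#' @export
multinomial_weights <- function(cohort, spec = ipw_spec(link = "multinomial")) {
  spec$link <- "multinomial"
  stabilized_weights(cohort, spec)
}

new_weight_set <- function(ws, spec, truncation_bounds = NULL, models = NULL) {
  structure(ws, class = c("weight_set", class(ws)),
            spec = spec, truncation_bounds = truncation_bounds, models = models)
}

#' Winsorize cumulative stabilized weights at pooled percentiles
#'
#' Percentiles use the inverse empirical distribution function (type-1
#' quantiles), so a bound at 100 k / n percent equals the k-th order
#' statistic. The bounds used are recorded in the result's
#' `truncation_bounds` attribute.
#'
#' @param weights A `weight_set`.
#' @param lower_pct,upper_pct Percentile bounds, `0 <= lower < upper <= 100`.
#' @return The truncated `weight_set`.
#' @export
truncate_weights <- function(weights, lower_pct = 1, upper_pct = 99) {
  stopifnot(lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
  lo <- if (lower_pct == 0) -Inf else quantile(weights$sw_cum, lower_pct / 100, type = 1)
  hi <- if (upper_pct == 100) Inf else quantile(weights$sw_cum, upper_pct / 100, type = 1)
  weights$sw_cum <- clamp(weights$sw_cum, lo, hi)
  attr(weights, "truncation_bounds") <- c(lower = unname(lo), upper = unname(hi))
  weights
}

#' Per-day weight diagnostics
#'
#' Mean, SD and range of the cumulative stabilized weights by ICU day. With
#' correctly specified models the per-day mean is close to 1; sustained
#' drift flags model misspecification or positivity problems.
#'
#' @param weights A `weight_set`.
#' @return Tibble with one row per day.
#' @export
weight_diagnostics <- function(weights) {
  weights |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$sw_cum),
                     sd = sd(.data$sw_cum), min = min(.data$sw_cum),
                     max = max(.data$sw_cum), .groups = "drop")
}

#' @method autoplot weight_set
#' @export
autoplot.weight_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sw_cum)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = NA) +
    ggplot2::scale_x_continuous(trans = "log10") +
    ggplot2::labs(x = "cumulative stabilized weight (log scale)", y = "person-days",
                  title = "Distribution of inverse-probability weights") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
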