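#' Per-variable missingness profile of the person-day panel
#'
#' @param cohort An `icu_cohort`.
#' @param variables Columns to profile; defaults to every day-level column
#'   except identifiers and outcome.
#' @return Tibble with `variable`, `n_missing`, `n_total`, `fraction`.
#' @export
missingness_profile <- function(cohort, variables = NULL) {
  days <- cohort$days
  if (is.null(variables)) {
    # concentration is exposure metadata: NA simply means no infusion that day
    variables <- setdiff(names(days),
                         c("patient_id", "day", "event", "concentration"))
  }
  tibble::tibble(
    variable = variables,
    n_missing = vapply(variables, function(v) sum(is.na(days[[v]])), integer(1),
                       USE.NAMES = FALSE),
    n_total = nrow(days)
  ) |>
    dplyr::mutate(fraction = .data$n_missing / .data$n_total)
}

#' Drop variables above the missingness threshold
#'
#' Variables with strictly more than `max_missing_fraction` missing values
#' (default 60\%) are removed from the panel; a variable at the boundary is
#' retained. Dropping a variable named in `required` (e.g. a confounder the
#' weight models need) is a hard error rather than a silent removal.
#'
#' @param cohort An `icu_cohort`.
#' @param max_missing_fraction Threshold in (0, 1].
#' @param required Character vector of variables that may not be dropped.
#' @return The reduced cohort, with the dropped-variable list in
#'   `meta$dropped_variables`.
#' @export
exclude_high_missing <- function(cohort, max_missing_fraction = 0.60,
                                 required = character()) {
  prof <- missingness_profile(cohort)
  drop <- prof$variable[prof$fraction > max_missing_fraction]
  bad <- intersect(drop, required)
  if (length(bad) > 0) {
    abort(paste0("configuration error: mandatory confounder(s) above the ",
                 "missingness threshold: ", paste(bad, collapse = ", ")),
          class = "albumsm_config_error")
  }
  cohort$days <- cohort$days[setdiff(names(cohort$days), drop)]
  cohort$meta$dropped_variables <- drop
  cohort
}

# one chained-equations pass over the variables with gaps; proper Bayesian
# coefficient draw, then inverse-distance-weighted donor sampling among the
# k nearest observed predictions (weighted predictive mean matching)
pmm_sweep <- function(x, miss_mask, targets, predictors, k_donors) {
  for (v in targets) {
    mis <- miss_mask[[v]]
    obs <- !mis
    preds <- setdiff(predictors, v)
    X <- cbind(1, as.matrix(x[preds]))
    y <- x[[v]]
    XtX <- crossprod(X[obs, , drop = FALSE])
    # ridge nudge for degenerate designs
    XtX <- XtX + diag(1e-8 * diag(XtX) + 1e-12)
    bhat <- solve(XtX, crossprod(X[obs, , drop = FALSE], y[obs]))
    res <- y[obs] - X[obs, , drop = FALSE] %*% bhat
    df <- max(sum(obs) - ncol(X), 1)
    sigma2 <- sum(res^2) / stats::rchisq(1, df)
    V <- chol(solve(XtX) * sigma2)
    bstar <- bhat + t(V) %*% rnorm(ncol(X))
    yhat_obs <- drop(X[obs, , drop = FALSE] %*% bhat)
    yhat_mis <- drop(X[mis, , drop = FALSE] %*% bstar)
    obs_vals <- y[obs]
    imp <- vapply(yhat_mis, function(p) {
      d <- abs(yhat_obs - p)
      k <- min(k_donors, length(d))
      nn <- order(d)[seq_len(k)]
      w <- 1 / (d[nn] + 1e-6)
      obs_vals[sample(nn, 1, prob = w / sum(w))]
    }, numeric(1))
    x[[v]][mis] <- imp
  }
  x
}

#' Multiple imputation by weighted predictive mean matching
#'
#' Chained-equations imputation of the day-level variables with missing
#' values. Each sweep regresses a target variable on the other time-varying
#' variables, the ICU day, the event indicator and a few baseline anchors,
#' draws regression coefficients from their posterior, and fills each gap
#' with the observed value of a donor sampled from the `k_donors` rows with
#' the nearest predicted values, with probability inversely proportional to
#' predictive distance. Observed cells are never altered, and imputed values
#' always come from the variable's observed support.
#'
#' @param cohort An `icu_cohort` (variables above the missingness threshold
#'   should have been removed first; see [exclude_high_missing()]).
#' @param m Number of completed cohorts (default 5).
#' @param k_donors Donor-pool size (default 5).
#' @param sweeps Chained-equation passes per imputation (default 10).
#' @param seed Integer seed.
#' @param baseline_predictors Baseline columns used as anchors.
#' @return List of `m` completed `icu_cohort`s, class `imputed_cohorts`.
#' @export
impute_pmm <- function(cohort, m = 5, k_donors = 5, sweeps = 10, seed = NULL,
                       baseline_predictors = c("age", "sofa0", "baseline_albumin")) {
  stopifnot(m >= 1, k_donors >= 1)
  if (!is.null(seed)) set.seed(seed)
  days <- cohort$days
  num_vars <- names(days)[vapply(days, is.numeric, logical(1))]
  num_vars <- setdiff(num_vars, c("day", "concentration", "albumin_dose"))
  targets <- num_vars[vapply(num_vars, function(v) anyNA(days[[v]]), logical(1))]
  if (length(targets) == 0) {
    out <- purrr::map(seq_len(m), ~ cohort)
    class(out) <- "imputed_cohorts"
    return(out)
  }
  for (v in targets) {
    if (sum(!is.na(days[[v]])) == 0) {
      abort(paste0("imputation error: variable '", v, "' has no observed values"),
            class = "albumsm_imputation_error")
    }
  }
  bp <- intersect(baseline_predictors, names(cohort$baselines))
  anchors <- dplyr::left_join(days["patient_id"],
                              cohort$baselines[c("patient_id", bp)],
                              by = "patient_id")[bp]
  x_base <- days
  x_base$.day <- as.numeric(days$day)
  x_base$.event <- as.numeric(days$event %||% 0)
  x_base$.treated <- as.numeric(days$treated %||% 0)
  for (b in bp) x_base[[paste0(".", b)]] <- as.numeric(anchors[[b]])
  predictors <- c(setdiff(num_vars, targets),
                  ".day", ".event", ".treated", paste0(".", bp))
  predictors <- predictors[vapply(predictors, function(p) !anyNA(x_base[[p]]) &&
                                    var(as.numeric(x_base[[p]])) > 0, logical(1))]
  all_preds <- union(predictors, targets)
  miss_mask <- lapply(days[targets], is.na)

  out <- purrr::map(seq_len(m), function(i) {
    x <- x_base
    # initialize gaps from the observed marginal distribution
    for (v in targets) {
      mis <- miss_mask[[v]]
      x[[v]][mis] <- sample(x[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (s in seq_len(sweeps)) {
      x <- pmm_sweep(x, miss_mask, targets, all_preds, k_donors)
    }
    comp <- cohort
    for (v in targets) comp$days[[v]] <- x[[v]]
    comp
  })
  class(out) <- "imputed_cohorts"
  out
}

#' Pool weighted Cox fits across imputations (Rubin's rules)
#'
#' Pooled coefficient = mean across imputations; total variance = mean
#' within-imputation variance + (1 + 1/m) times the between-imputation
#' variance. Confidence intervals use the normal approximation on the log
#' hazard ratio scale.
#'
#' @param fits List of `mscm_fit` objects on the same model.
#' @return Tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `within_var`, `between_var`, `hr`, `conf.low`, `conf.high`, `p.value`,
#'   `m`.
#' @export
pool_estimates <- function(fits) {
  stopifnot(length(fits) >= 1)
  nms <- names(fits[[1]]$coefficients)
  for (f in fits) {
    if (!identical(names(f$coefficients), nms)) {
      abort("input error: fits have mismatched coefficient names",
            class = "albumsm_input_error")
    }
  }
  m <- length(fits)
  q <- vapply(fits, function(f) f$coefficients, numeric(length(nms)))
  u <- vapply(fits, function(f) f$se_robust^2, numeric(length(nms)))
  q <- matrix(q, nrow = length(nms))
  u <- matrix(u, nrow = length(nms))
  qbar <- rowMeans(q)
  wbar <- rowMeans(u)
  b <- if (m > 1) apply(q, 1, var) else rep(0, length(nms))
  total <- wbar + (1 + 1 / m) * b
  se <- sqrt(total)
  z <- qbar / se
  tibble::tibble(term = nms, estimate = qbar, std.error = se,
                 within_var = wbar, between_var = b,
                 hr = exp(qbar),
                 conf.low = exp(qbar - qnorm(0.975) * se),
                 conf.high = exp(qbar + qnorm(0.975) * se),
                 p.value = 2 * pnorm(-abs(z)), m = m)
}
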