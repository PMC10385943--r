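#' Baseline group comparisons (Table-1 style)
#'
#' Compares ever-treated versus never-treated patients variable by variable:
#' categorical variables by the chi-square test, switching to Fisher's exact
#' test when any expected cell count falls below 5; continuous variables by
#' Student's t-test when an approximate-normality screen passes (absolute
#' skewness at most 1), otherwise the Mann-Whitney U test. Continuous
#' summaries are mean (SD) under the t-test and median \[IQR\] otherwise;
#' categorical summaries are n (\%).
#'
#' @param cohort An `icu_cohort` with a `treated` day column.
#' @param variables Baseline columns to compare; defaults to every baseline
#'   column except identifiers and times.
#' @param skew_cutoff Absolute-skewness bound of the normality screen.
#' @return Tibble with `variable`, `summary_never`, `summary_ever`, `test`,
#'   `statistic`, `p.value`.
#' @export
compare_groups <- function(cohort, variables = NULL, skew_cutoff = 1) {
  os <- outcome_summary(cohort)
  b <- dplyr::left_join(cohort$baselines, os[c("patient_id", "ever_treated")],
                        by = "patient_id")
  if (is.null(variables)) {
    variables <- setdiff(names(cohort$baselines),
                         c("patient_id", "icu_admit_time", "hospital_admit_time",
                           "sepsis_onset_time", "icu_stay_index"))
  }
  miss <- setdiff(variables, names(b))
  if (length(miss) > 0) {
    abort(paste0("schema error: no baseline column(s): ",
                 paste(miss, collapse = ", ")),
          class = "albumsm_schema_error")
  }
  g <- factor(ifelse(b$ever_treated, "ever", "never"), levels = c("never", "ever"))
  rows <- purrr::map(variables, function(v) {
    x <- b[[v]]
    if (is.numeric(x)) {
      sk <- skewness(x)
      if (is.finite(sk) && abs(sk) <= skew_cutoff) {
        ts <- t.test(x ~ g)
        smry <- vapply(levels(g), function(l) {
          sprintf("%.1f (%.1f)", mean(x[g == l], na.rm = TRUE),
                  sd(x[g == l], na.rm = TRUE))
        }, character(1))
        tibble::tibble(variable = v, summary_never = smry[1],
                       summary_ever = smry[2], test = "t",
                       statistic = unname(ts$statistic), p.value = ts$p.value)
      } else {
        ws <- wilcox.test(x ~ g, exact = FALSE)
        smry <- vapply(levels(g), function(l) {
          q <- quantile(x[g == l], c(0.25, 0.5, 0.75), na.rm = TRUE)
          sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3])
        }, character(1))
        tibble::tibble(variable = v, summary_never = smry[1],
                       summary_ever = smry[2], test = "mann-whitney",
                       statistic = unname(ws$statistic), p.value = ws$p.value)
      }
    } else {
      tab <- table(factor(x), g)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      smry <- vapply(levels(g), function(l) {
        paste(sprintf("%s %d (%.0f%%)", rownames(tab), tab[, l],
                      100 * tab[, l] / sum(tab[, l])), collapse = "; ")
      }, character(1))
      if (any(expected < 5)) {
        ft <- fisher.test(tab, simulate.p.value = nrow(tab) > 2)
        tibble::tibble(variable = v, summary_never = smry[1],
                       summary_ever = smry[2], test = "fisher",
                       statistic = NA_real_, p.value = ft$p.value)
      } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        tibble::tibble(variable = v, summary_never = smry[1],
                       summary_ever = smry[2], test = "chi-square",
                       statistic = unname(ct$statistic), p.value = ct$p.value)
      }
    }
  })
  dplyr::bind_rows(rows)
}

skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || sd(x) == 0) return(0)
  mean((x - mean(x))^3) / sd(x)^3
}

#' ICU-free and hospital-free days at the horizon
#'
#' Free days are `max(0, horizon - days in unit)` for patients surviving to
#' the horizon; patients who die within the horizon score 0 by convention
#' (set `decedents_zero = FALSE` to count their unit-free days regardless).
#'
#' @param cohort An `icu_cohort` whose baselines carry `icu_los` and
#'   `hospital_los` in hours.
#' @param horizon Horizon in days (default 28).
#' @param decedents_zero Convention switch described above.
#' @return Tibble with `patient_id`, `died`, `icu_free_days`,
#'   `hospital_free_days`.
#' @export
compute_free_days <- function(cohort, horizon = 28, decedents_zero = TRUE) {
  b <- cohort$baselines
  if (any(b$icu_los < 0, na.rm = TRUE) || any(b$hospital_los < 0, na.rm = TRUE)) {
    abort("input error: negative length of stay", class = "albumsm_input_error")
  }
  os <- outcome_summary(cohort)
  out <- dplyr::left_join(os[c("patient_id", "died")],
                          b[c("patient_id", "icu_los", "hospital_los")],
                          by = "patient_id") |>
    dplyr::mutate(
      icu_free_days = pmax(0, horizon - .data$icu_los / 24),
      hospital_free_days = pmax(0, horizon - .data$hospital_los / 24)
    )
  if (decedents_zero) {
    out$icu_free_days[out$died] <- 0
    out$hospital_free_days[out$died] <- 0
  }
  out[c("patient_id", "died", "icu_free_days", "hospital_free_days")]
}

#' Forest-style plot of indication sub-cohort hazard ratios
#' @param results Tibble with columns `label`, `hr`, `conf.low`, `conf.high`.
#' @return A ggplot object.
#' @export
plot_forest <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$hr, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_continuous(trans = "log10") +
    ggplot2::labs(x = "hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
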