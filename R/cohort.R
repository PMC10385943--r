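#' Construct a longitudinal ICU cohort
#'
#' Bundles a per-patient baseline table and a long person-day panel (one row
#' per patient per ICU day) into a validated `icu_cohort` object, the unit of
#' data every analysis function in the package consumes. Rows beyond `horizon`
#' are dropped (administrative censoring); all other invariant violations are
#' errors with row-addressed messages.
#'
#' @param baselines Data frame with one row per patient. Must contain
#'   `patient_id`; analysis stages require the columns they use (e.g. the
#'   inclusion filters need `icu_los`, `hospital_los`, `icu_admit_time`,
#'   `sepsis_onset_time`, `icu_stay_index`).
#' @param days Data frame with one row per patient-day: `patient_id`, `day`
#'   (integer, consecutive from 1 while at risk), time-varying covariates,
#'   `treated`/`albumin_dose` exposure columns and a logical `event` column
#'   marking death in that day's risk interval.
#' @param horizon Follow-up horizon in days (default 28).
#' @param meta Optional named list of provenance/configuration notes.
#'
#' @return An object of class `icu_cohort`: a list with elements `baselines`,
#'   `days` (tibbles), `horizon` and `meta`.
#' @examples
#' b <- tibble::tibble(patient_id = "p1", age = 60)
#' d <- tibble::tibble(patient_id = "p1", day = 1:3, treated = c(FALSE, TRUE, TRUE),
#'                     event = c(FALSE, FALSE, TRUE))
#' icu_cohort(b, d)
#' @export
icu_cohort <- function(baselines, days, horizon = 28, meta = list()) {
  baselines <- tibble::as_tibble(baselines)
  days <- tibble::as_tibble(days)
  for (col in "patient_id") {
    if (!col %in% names(baselines)) {
      abort(paste0("schema error: baseline table lacks mandatory column '", col, "'"),
            class = "albumsm_schema_error")
    }
  }
  for (col in c("patient_id", "day")) {
    if (!col %in% names(days)) {
      abort(paste0("schema error: person-day table lacks mandatory column '", col, "'"),
            class = "albumsm_schema_error")
    }
  }
  days$day <- as.integer(days$day)
  dup <- days[duplicated(days[c("patient_id", "day")]), , drop = FALSE]
  if (nrow(dup) > 0) {
    abort(paste0("integrity error: duplicated patient-day row(s): ",
                 paste(paste0(dup$patient_id, "/", dup$day), collapse = ", ")),
          class = "albumsm_integrity_error")
  }
  if (anyDuplicated(baselines$patient_id)) {
    abort("integrity error: duplicated patient_id in baseline table",
          class = "albumsm_integrity_error")
  }
  orphan <- setdiff(unique(days$patient_id), baselines$patient_id)
  if (length(orphan) > 0) {
    abort(paste0("integrity error: person-day rows without baseline record: ",
                 paste(head(orphan, 5), collapse = ", ")),
          class = "albumsm_integrity_error")
  }
  days <- dplyr::arrange(days, .data$patient_id, .data$day)
  days <- dplyr::filter(days, .data$day <= horizon)
  bad <- days |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ok = all(.data$day == seq_along(.data$day)), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("integrity error: days not consecutive from 1 for patient(s): ",
                 paste(head(bad$patient_id, 5), collapse = ", ")),
          class = "albumsm_integrity_error")
  }
  if ("event" %in% names(days)) {
    days$event <- as.logical(days$event)
    ev <- days |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        n_event = sum(.data$event),
        last_ok = sum(.data$event) == 0 || .data$event[dplyr::n()],
        .groups = "drop"
      )
    if (any(ev$n_event > 1)) {
      abort(paste0("integrity error: more than one event for patient(s): ",
                   paste(head(ev$patient_id[ev$n_event > 1], 5), collapse = ", ")),
            class = "albumsm_integrity_error")
    }
    if (any(!ev$last_ok)) {
      abort(paste0("integrity error: event before final at-risk day for patient(s): ",
                   paste(head(ev$patient_id[!ev$last_ok], 5), collapse = ", ")),
            class = "albumsm_integrity_error")
    }
  }
  if (all(c("treated", "albumin_dose") %in% names(days))) {
    off <- which(days$treated != (days$albumin_dose > 0))
    if (length(off) > 0) {
      abort(paste0("integrity error: treated flag inconsistent with albumin_dose on ",
                   length(off), " row(s), e.g. ",
                   days$patient_id[off[1]], "/", days$day[off[1]]),
            class = "albumsm_integrity_error")
    }
  }
  structure(
    list(baselines = baselines, days = days, horizon = as.integer(horizon), meta = meta),
    class = "icu_cohort"
  )
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat("<icu_cohort> ", nrow(x$baselines), " patients, ", nrow(x$days),
      " person-days, horizon ", x$horizon, " d\n", sep = "")
  if ("event" %in% names(x$days)) {
    cat("  deaths: ", sum(x$days$event), " (",
        round(100 * sum(x$days$event) / nrow(x$baselines), 1), "%)\n", sep = "")
  }
  if ("treated" %in% names(x$days)) {
    ever <- x$days |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(t = any(.data$treated), .groups = "drop")
    cat("  ever treated: ", sum(ever$t), " (",
        round(100 * mean(ever$t), 1), "%)\n", sep = "")
  }
  invisible(x)
}

#' @method as_tibble icu_cohort
#' @export
as_tibble.icu_cohort <- function(x, ...) {
  dplyr::left_join(x$days, x$baselines, by = "patient_id",
                   suffix = c("", "_baseline"))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Number of patients in a cohort
#' @param cohort An `icu_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$baselines)

#' Per-patient outcome summary
#'
#' Collapses the person-day panel to one row per patient: last at-risk day,
#' death indicator, and whether the patient was ever treated.
#'
#' @param cohort An `icu_cohort`.
#' @return Tibble with `patient_id`, `time` (last at-risk day), `died`,
#'   `ever_treated`, `first_treated_day` (NA when never treated).
#' @export
outcome_summary <- function(cohort) {
  cohort$days |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      time = max(.data$day),
      died = if ("event" %in% names(cohort$days)) any(.data$event) else NA,
      ever_treated = if ("treated" %in% names(cohort$days)) any(.data$treated) else NA,
      first_treated_day = if ("treated" %in% names(cohort$days) && any(.data$treated)) {
        min(.data$day[.data$treated])
      } else NA_integer_,
      .groups = "drop"
    )
}

#' Read a longitudinal cohort from delimited text
#'
#' Reads the person-day panel and baseline table from CSV and validates them
#' into an [icu_cohort()]. An optional schema maps non-standard column names
#' onto the package's canonical ones.
#'
#' @param days_path Path to the person-day CSV.
#' @param baselines_path Path to the baseline CSV.
#' @param schema Optional named character vector or list, `canonical = "file_column"`,
#'   applied to both tables where the file column exists.
#' @param horizon Follow-up horizon in days.
#' @return An `icu_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(days_path, baselines_path, schema = NULL, horizon = 28) {
  days <- readr::read_csv(days_path, show_col_types = FALSE, progress = FALSE)
  baselines <- readr::read_csv(baselines_path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    schema <- unlist(schema)
    rename_with_schema <- function(df) {
      hit <- schema[schema %in% names(df)]
      names(df)[match(hit, names(df))] <- names(hit)
      df
    }
    days <- rename_with_schema(days)
    baselines <- rename_with_schema(baselines)
  }
  icu_cohort(baselines, days, horizon = horizon,
             meta = list(source = c(days = days_path, baselines = baselines_path)))
}

#' Write a cohort to delimited text
#'
#' @param cohort An `icu_cohort`.
#' @param days_path,baselines_path Output CSV paths.
#' @return The cohort, invisibly.
#' @export
write_cohort <- function(cohort, days_path, baselines_path) {
  readr::write_csv(cohort$days, days_path, progress = FALSE)
  readr::write_csv(cohort$baselines, baselines_path, progress = FALSE)
  invisible(cohort)
}

#' Apply the study inclusion and exclusion filters
#'
#' Retains first ICU stays of at least 24 h and at most 100 days, hospital
#' stays of at least 24 h, and sepsis onset within a window around ICU
#' admission. The exclusion tally (patients removed per criterion, in
#' application order) is attached to the result's `meta$exclusions` and
#' retrievable with [exclusion_tally()].
#'
#' @param cohort An `icu_cohort` whose baselines carry `icu_los` and
#'   `hospital_los` (hours), `icu_admit_time` and `sepsis_onset_time` (hours on
#'   a common clock) and `icu_stay_index`.
#' @param sepsis_window Two-element numeric vector, hours relative to ICU
#'   admission within which sepsis onset must fall (default `c(-12, 24)`).
#' @param icu_los_range Allowed ICU length of stay in hours (default 24 h to
#'   100 days).
#' @param min_hospital_los Minimum hospital stay in hours.
#' @return Filtered `icu_cohort`.
#' @export
apply_inclusion_filters <- function(cohort,
                                    sepsis_window = c(-12, 24),
                                    icu_los_range = c(24, 100 * 24),
                                    min_hospital_los = 24) {
  b <- cohort$baselines
  need <- c("icu_los", "hospital_los", "icu_admit_time", "sepsis_onset_time",
            "icu_stay_index")
  miss <- setdiff(need, names(b))
  if (length(miss) > 0) {
    abort(paste0("schema error: inclusion filters need baseline column(s): ",
                 paste(miss, collapse = ", ")),
          class = "albumsm_schema_error")
  }
  tally <- list()
  step <- function(keep, reason) {
    tally[[reason]] <<- sum(!keep)
    b <<- b[keep, , drop = FALSE]
  }
  step(b$hospital_los >= min_hospital_los, "hospital_los<24h")
  onset <- b$sepsis_onset_time - b$icu_admit_time
  step(onset >= sepsis_window[1] & onset <= sepsis_window[2], "sepsis_onset_outside_window")
  step(b$icu_los >= icu_los_range[1], "icu_los<24h")
  step(b$icu_los <= icu_los_range[2], "icu_los>100d")
  step(b$icu_stay_index == 1, "not_first_icu_stay")
  days <- dplyr::semi_join(cohort$days, b, by = "patient_id")
  out <- icu_cohort(b, days, horizon = cohort$horizon, meta = cohort$meta)
  out$meta$exclusions <- tibble::tibble(
    criterion = names(tally),
    n_excluded = unlist(tally, use.names = FALSE)
  )
  out
}

#' Exclusion tally from the last filter application
#' @param cohort A filtered `icu_cohort`.
#' @return Tibble with `criterion` and `n_excluded`, or `NULL` if the cohort
#'   has not been filtered.
#' @export
exclusion_tally <- function(cohort) cohort$meta$exclusions

#' Collapse repeated daily measurements to the worst value
#'
#' When a variable is charted more than once on an ICU day, the value
#' reflecting the greatest severity of illness is kept: the maximum for
#' variables where higher is worse (lactate, SOFA, vasopressor dose), the
#' minimum where lower is worse (MAP, P/F ratio, urine output).
#'
#' @param measurements Tibble of raw charted values with columns `patient_id`,
#'   `day`, `variable`, `value`.
#' @param direction_map Named character vector mapping each variable to
#'   `"max_is_worst"` or `"min_is_worst"`; see [worst_value_directions()].
#' @return Wide tibble, one row per patient-day, one column per variable;
#'   `NA` where a variable was not measured that day.
#' @examples
#' m <- tibble::tibble(patient_id = "p1", day = 3,
#'                     variable = c("map", "map", "lactate"),
#'                     value = c(70, 55, 3.2))
#' collapse_daily_worst(m)
#' @export
collapse_daily_worst <- function(measurements, direction_map = worst_value_directions()) {
  vars <- unique(measurements$variable)
  unknown <- setdiff(vars, names(direction_map))
  if (length(unknown) > 0) {
    abort(paste0("configuration error: no worst-value direction for variable(s): ",
                 paste(unknown, collapse = ", ")),
          class = "albumsm_config_error")
  }
  measurements |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$patient_id, .data$day, .data$variable) |>
    dplyr::summarise(
      value = if (direction_map[[.data$variable[1]]] == "max_is_worst") {
        max(.data$value)
      } else {
        min(.data$value)
      },
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
}

#' Default worst-value directions for daily collapsing
#'
#' Clinical conventions: severity increases with lactate, SOFA, vasopressor
#' dose, bilirubin and creatinine, and decreases with MAP, P/F ratio, urine
#' output, platelets and serum albumin. Override by passing an edited copy to
#' [collapse_daily_worst()].
#' @return Named character vector.
#' @export
worst_value_directions <- function() {
  c(lactate = "max_is_worst", sofa = "max_is_worst", vaso_nee = "max_is_worst",
    bilirubin = "max_is_worst", creatinine = "max_is_worst",
    map = "min_is_worst", pf_ratio = "min_is_worst", urine_output = "min_is_worst",
    platelet = "min_is_worst", serum_albumin = "min_is_worst")
}

#' Daily albumin dose in g/kg and dose stratum
#'
#' Dose = sum over infusions of volume (mL) x concentration (g/mL fraction),
#' divided by body weight (kg). Strata use upper-closed boundaries:
#' none (0), low (0, 0.5], mid (0.5, 1.0], high (1.0, 1.5], vhigh (> 1.5).
#'
#' @param volume_ml Numeric vector of infusion volumes (mL).
#' @param concentration Numeric vector of solution concentrations as fractions
#'   (25\% albumin = 0.25); must lie in (0, 1].
#' @param weight Body weight in kg (scalar).
#' @return Dose in g/kg (scalar).
#' @examples
#' compute_albumin_dose(c(100, 500), c(0.25, 0.05), weight = 80)  # 0.625 g/kg
#' @export
compute_albumin_dose <- function(volume_ml, concentration, weight) {
  stopifnot(length(volume_ml) == length(concentration))
  if (length(weight) != 1 || !is.finite(weight) || weight <= 0) {
    abort("input error: weight must be a positive scalar (kg)",
          class = "albumsm_input_error")
  }
  if (length(volume_ml) == 0) return(0)
  if (any(volume_ml < 0)) {
    abort("input error: negative infusion volume", class = "albumsm_input_error")
  }
  if (any(concentration <= 0 | concentration > 1)) {
    abort("input error: concentration must lie in (0, 1] as a g/mL fraction",
          class = "albumsm_input_error")
  }
  sum(volume_ml * concentration) / weight
}

#' @rdname compute_albumin_dose
#' @param dose Numeric vector of daily doses in g/kg.
#' @return `dose_stratum()`: ordered factor with levels
#'   `none < low < mid < high < vhigh`.
#' @export
dose_stratum <- function(dose) {
  cut(dose, breaks = c(-Inf, 0, 0.5, 1.0, 1.5, Inf),
      labels = c("none", "low", "mid", "high", "vhigh"),
      right = TRUE, ordered_result = TRUE)
}

#' Norepinephrine-equivalent vasopressor dose
#'
#' Combines concurrent vasopressor infusion rates into a single
#' norepinephrine-equivalent (NEE) rate, mcg/kg/min, by a conversion-factor
#' table.
#'
#' @param rates Named numeric vector of infusion rates (mcg/kg/min, except
#'   vasopressin in U/min).
#' @param conversion Named numeric vector of multiplicative factors; see
#'   [nee_conversion()].
#' @return NEE dose (scalar, mcg/kg/min).
#' @examples
#' compute_nee(c(norepinephrine = 0.1, epinephrine = 0.05))
#' @export
compute_nee <- function(rates, conversion = nee_conversion()) {
  if (length(rates) == 0) return(0)
  if (any(rates < 0)) {
    abort("input error: vasopressor rates must be nonnegative",
          class = "albumsm_input_error")
  }
  unknown <- setdiff(names(rates), names(conversion))
  if (length(unknown) > 0) {
    abort(paste0("configuration error: no NEE conversion factor for: ",
                 paste(unknown, collapse = ", ")),
          class = "albumsm_config_error")
  }
  sum(rates * conversion[names(rates)])
}

#' Default NEE conversion factors
#'
#' Norepinephrine and epinephrine 1:1; dopamine 1:100; phenylephrine 1:10;
#' vasopressin 0.04 U/min equivalent to 0.1 mcg/kg/min norepinephrine
#' (factor 2.5 per U/min). Editable: pass a modified copy to [compute_nee()].
#' @return Named numeric vector.
#' @export
nee_conversion <- function() {
  c(norepinephrine = 1, epinephrine = 1, dopamine = 0.01,
    phenylephrine = 0.1, vasopressin = 2.5)
}

#' Flag septic shock on a person-day panel
#'
#' Septic shock on a day is vasopressor use together with serum lactate
#' strictly greater than 2 mmol/L. Missing lactate propagates as `NA`.
#'
#' @param days Tibble with `vaso_nee` and `lactate` columns.
#' @return The tibble with a logical `septic_shock` column added.
#' @export
flag_septic_shock <- function(days) {
  dplyr::mutate(days, septic_shock = .data$vaso_nee > 0 &
                  ifelse(is.na(.data$lactate), NA, .data$lactate > 2.0))
}
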