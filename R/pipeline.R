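#' Default pipeline configuration
#'
#' @param scenario Simulation scenario name (see [sim_scenario()]), used when
#'   no input files are given.
#' @param n_patients Cohort size for simulated input.
#' @param days_path,baselines_path Optional CSV paths for real input.
#' @param seed Integer seed governing every random stage.
#' @param missingness Optional named rates handed to [inject_missingness()];
#'   triggers multiple imputation.
#' @param m Number of imputations when imputation runs.
#' @param cutpoints Heaviside cutpoints.
#' @param run_searches,run_subgroups,run_sensitivity Stage switches.
#' @param subgroup_vars Baseline columns for subgroup analyses.
#' @param sensitivity_flag Baseline flag excluded in the sensitivity run.
#' @param truncation Weight-truncation percentiles or `NULL`.
#' @return A config list for [run_pipeline()].
#' @export
pipeline_config <- function(scenario = "paper_like", n_patients = 1000,
                            days_path = NULL, baselines_path = NULL,
                            seed = 1, missingness = NULL, m = 5,
                            cutpoints = c(7, 14, 21),
                            run_searches = FALSE, run_subgroups = FALSE,
                            run_sensitivity = FALSE,
                            subgroup_vars = c("aki_flag"),
                            sensitivity_flag = "sbp_flag",
                            truncation = c(1, 99)) {
  list(scenario = scenario, n_patients = n_patients, days_path = days_path,
       baselines_path = baselines_path, seed = seed, missingness = missingness,
       m = m, cutpoints = cutpoints, run_searches = run_searches,
       run_subgroups = run_subgroups, run_sensitivity = run_sensitivity,
       subgroup_vars = subgroup_vars, sensitivity_flag = sensitivity_flag,
       truncation = truncation)
}

check_config <- function(config, field, stage) {
  if (is.null(config[[field]])) {
    abort(paste0("configuration error in stage '", stage, "': missing field '",
                 field, "'"),
          class = "albumsm_config_error")
  }
  config[[field]]
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the study end to end: load or simulate the cohort, apply the
#' inclusion filters, (optionally) inject missingness and multiply impute,
#' estimate stabilized weights, fit the overall marginal structural Cox
#' model, the crude model, the Heaviside period model, the weighted
#' Kaplan-Meier curves, and optionally the indication searches, subgroup and
#' sensitivity analyses. The result bundle is a plain list of tibbles and
#' numbers, reproducible byte for byte from the same configuration and seed.
#'
#' @param config A [pipeline_config()] list or the path to a YAML file with
#'   the same fields.
#' @return A `pipeline_result` list.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(n_patients = 300, seed = 7))
#' res$mscm_overall
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- check_config(config, "seed", "setup")

  # --- input -------------------------------------------------------------
  if (!is.null(config$days_path)) {
    cohort <- read_cohort(config$days_path,
                          check_config(config, "baselines_path", "input"))
  } else {
    scen <- check_config(config, "scenario", "input")
    cohort <- simulate_cohort(
      sim_scenario(scen, n_patients = check_config(config, "n_patients", "input")),
      seed = seed)
  }
  cohort <- apply_inclusion_filters(cohort)

  # --- missing data ------------------------------------------------------
  completed <- list(cohort)
  imputed <- FALSE
  if (!is.null(config$missingness)) {
    cohort <- inject_missingness(cohort, unlist(config$missingness),
                                 seed = seed + 1)
    cohort <- exclude_high_missing(cohort)
    completed <- impute_pmm(cohort, m = config$m %||% 5, seed = seed + 2)
    imputed <- TRUE
  }

  spec <- ipw_spec(truncation = config$truncation)
  fit_once <- function(co) {
    w <- suppressWarnings(stabilized_weights(co, spec))
    rec <- build_counting_process(co, weights = w)
    list(weights = w, records = rec,
         mscm = fit_weighted_cox(rec),
         crude = fit_weighted_cox(dplyr::mutate(rec, weight = 1)),
         heaviside = heaviside_fit(rec, cutpoints = config$cutpoints %||% c(7, 14, 21)))
  }
  fits <- purrr::map(completed, fit_once)
  main <- fits[[1]]

  mscm_overall <- if (imputed) {
    pool_estimates(purrr::map(fits, "mscm"))
  } else {
    tidy(main$mscm)
  }

  result <- list(
    config = config,
    n_patients = n_patients(completed[[1]]),
    n_person_days = nrow(completed[[1]]$days),
    exclusions = exclusion_tally(completed[[1]]),
    table1 = compare_groups(completed[[1]]),
    weight_diagnostics = weight_diagnostics(main$weights),
    mscm_overall = mscm_overall,
    crude = tidy(main$crude),
    heaviside = main$heaviside$period_hrs,
    km = tibble::as_tibble(weighted_km(main$records)),
    free_days = compute_free_days(completed[[1]]),
    imputed = imputed
  )

  base_cohort <- completed[[1]]
  if (isTRUE(config$run_searches)) {
    result$albumin_search <- albumin_threshold_search(base_cohort, spec = spec)
    result$lactate_search <- lactate_threshold_search(base_cohort, spec = spec)
    bins <- albumin_indication_bins()
    result$indication_forest <- dplyr::bind_rows(purrr::map(bins, function(r) {
      sub <- suppressWarnings(build_subcohort(base_cohort, r))
      fit <- tryCatch(suppressWarnings(
        evaluate_indication(sub, spec, n_family = length(bins))),
        error = function(e) NULL)
      if (is.null(fit)) {
        return(tibble::tibble(label = format(r), n_treated = sub$meta$indication$n_treated,
                              hr = NA_real_, conf.low = NA_real_,
                              conf.high = NA_real_, p.value = NA_real_))
      }
      td <- tidy(fit)[1, ]
      tibble::tibble(label = format(r), n_treated = sub$meta$indication$n_treated,
                     hr = td$hr, conf.low = td$conf.low, conf.high = td$conf.high,
                     p.value = td$p.value)
    }))
  }
  if (isTRUE(config$run_subgroups)) {
    result$subgroups <- purrr::map(
      setNames(config$subgroup_vars, config$subgroup_vars),
      ~ subgroup_analysis(base_cohort, .x, spec = spec))
  }
  if (isTRUE(config$run_sensitivity)) {
    sens <- sensitivity_exclude(base_cohort, config$sensitivity_flag %||% "sbp_flag")
    w <- suppressWarnings(stabilized_weights(sens, spec))
    result$sensitivity <- tidy(fit_weighted_cox(build_counting_process(sens, weights = w)))
  }
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$n_patients, " patients, ", x$n_person_days,
      " person-days\n", sep = "")
  cat("overall MSCM:\n")
  print(as.data.frame(x$mscm_overall), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Tables go to CSV, scalars and metadata to a single JSON file. Re-rendering
#' is a pure function of the bundle: nothing is recomputed.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("table1", "weight_diagnostics", "mscm_overall", "crude",
              "heaviside", "km", "free_days", "exclusions", "indication_forest")
  for (t in tables) {
    if (!is.null(result[[t]])) {
      readr::write_csv(result[[t]], file.path(dir, paste0(t, ".csv")),
                       progress = FALSE)
    }
  }
  meta <- list(n_patients = result$n_patients,
               n_person_days = result$n_person_days,
               imputed = result$imputed,
               albumin_trigger = result$albumin_search$threshold,
               lactate_trigger = result$lactate_search$threshold,
               config = result$config[setdiff(names(result$config), c())])
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(meta, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    saveRDS(meta, file.path(dir, "summary.rds"))
  }
  invisible(dir)
}
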