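#' Simulation parameters for a synthetic septic-cirrhosis ICU cohort
#'
#' Defines the generating model for a longitudinal person-day cohort with
#' treatment-confounder feedback and a known conditional causal log-hazard
#' ratio. Daily time-varying covariates evolve by linear-Gaussian kernels on
#' transformed scales (log lactate, raw MAP, bounded serum albumin, integer
#' SOFA); daily treatment follows a logistic model in the current confounders
#' and treatment history; death in each day's risk interval follows a
#' complementary-log-log daily hazard so that `out_coefs["treated"]` is a
#' conditional log hazard ratio; past treatment feeds back into next-day
#' confounders. Defaults emulate the magnitudes of a septic-cirrhosis ICU
#' population (roughly 30\% in-ICU 28-day mortality, close to half of
#' patients ever treated, median lactate near 2.2 mmol/L); those magnitudes
#' are descriptive targets, not contracts.
#'
#' @param n_patients Number of patients.
#' @param horizon Follow-up horizon in days; rows stop at the horizon
#'   (administrative censoring).
#' @param treat_coefs Named vector of logistic coefficients for daily
#'   treatment: `intercept`, `sofa`, `log_lactate`, `map`, `vaso`,
#'   `serum_albumin`, `prev_treat`. Covariates are centered at sofa 5,
#'   log(2.2) mmol/L, 65 mmHg, 2.8 g/dL.
#' @param out_coefs Named vector for the daily hazard on the cloglog scale:
#'   `log_lambda0`, `treated` (the conditional causal log HR), `sofa`,
#'   `log_lactate`, `map`, `vaso`, `age`.
#' @param feedback Named vector: additive effect of yesterday's treatment on
#'   today's `sofa`, `log_lactate`, `map` and `serum_albumin`.
#' @param discharge_rate Daily probability of discharge alive (independent of
#'   covariates, i.e. noninformative censoring), from day 2 on.
#' @param dose_meanlog,dose_sdlog Log-normal parameters of the daily dose
#'   (g/kg) given treatment.
#' @param alb_classes,lac_classes Latent mixture classes for the serum-albumin
#'   and lactate processes: lists with vectors `frac`, `mean` (log scale for
#'   lactate), `init_sd`, `ar`, `innov_sd`. Single-class by default; the
#'   threshold-recovery scenarios use two classes to concentrate treatment
#'   initiations around a designed trigger.
#' @param effect_mod Optional effect modification by the value of a trigger
#'   variable on the patient's first treated day: list with `variable`
#'   (`"serum_albumin"` or `"lactate"`), `breaks` (full break vector including
#'   `-Inf`/`Inf`, left-closed) and `betas` (log HRs per band, replacing
#'   `out_coefs["treated"]` for that patient).
#' @return A `sim_params` list.
#' @seealso [sim_scenario()] for named presets, [simulate_cohort()],
#'   [marginal_hr_oracle()]
#' @export
sim_params <- function(n_patients = 2500,
                       horizon = 28,
                       treat_coefs = c(intercept = -2.2, sofa = 0.12,
                                       log_lactate = 0.5, map = -0.02,
                                       vaso = 0.4, serum_albumin = -0.6,
                                       prev_treat = 1.4),
                       out_coefs = c(log_lambda0 = log(0.045),
                                     treated = log(0.75), sofa = 0.17,
                                     log_lactate = 0.55, map = -0.025,
                                     vaso = 0.6, age = 0.015),
                       feedback = c(sofa = -0.05, log_lactate = -0.02,
                                    map = 0.3, serum_albumin = 0.25),
                       discharge_rate = 0.15,
                       dose_meanlog = log(0.62), dose_sdlog = 0.55,
                       alb_classes = list(frac = 1, mean = 2.8, init_sd = 0.5,
                                          ar = 0.9, innov_sd = 0.12),
                       lac_classes = list(frac = 1, mean = log(2.2),
                                          init_sd = 0.45, ar = 0.65,
                                          innov_sd = 0.30),
                       effect_mod = NULL) {
  if (horizon < 1) abort("horizon must be >= 1", class = "albumsm_input_error")
  lam0 <- 1 - exp(-exp(out_coefs[["log_lambda0"]]))
  if (!(lam0 > 0 && lam0 < 1)) {
    abort("baseline daily hazard must lie in (0, 1)", class = "albumsm_input_error")
  }
  if (discharge_rate < 0 || discharge_rate > 1) {
    abort("discharge_rate must lie in [0, 1]", class = "albumsm_input_error")
  }
  structure(
    list(n_patients = n_patients, horizon = as.integer(horizon),
         treat_coefs = treat_coefs, out_coefs = out_coefs,
         feedback = feedback, discharge_rate = discharge_rate,
         dose_meanlog = dose_meanlog, dose_sdlog = dose_sdlog,
         alb_classes = alb_classes, lac_classes = lac_classes,
         effect_mod = effect_mod),
    class = "sim_params"
  )
}

#' Named simulation scenarios
#'
#' * `"paper_like"`: the default confounded cohort with a beneficial
#'   treatment (conditional HR 0.75) and feedback.
#' * `"null_confounded"`: identical confounding structure with a truly null
#'   treatment effect — the crude hazard ratio is biased away from 1 while
#'   the weighted estimator should not be.
#' * `"feedback"`: conditional HR 0.70 with treatment-confounder feedback;
#'   the recovery target is [marginal_hr_oracle()].
#' * `"no_confounding"`: treatment assigned independently of the confounders
#'   (history-only), no feedback; crude and weighted estimates agree.
#' * `"albumin_threshold"`: benefit (HR 0.4) only for patients whose serum
#'   albumin on the first treated day is below 2.7 g/dL, an adverse effect
#'   (HR 6) above; a two-class albumin process concentrates initiations
#'   around the trigger so the upward 0.1 g/dL search can identify it.
#' * `"lactate_threshold"`: mirrored design, benefit (HR 0.3) only at
#'   initiation lactate >= 2.2 mmol/L, adverse below, two-class lactate
#'   process.
#'
#' @param name Scenario name.
#' @param n_patients Number of patients.
#' @param ... Named `sim_params` fields to override.
#' @return A `sim_params` object.
#' @export
sim_scenario <- function(name = c("paper_like", "null_confounded", "feedback",
                                  "no_confounding", "albumin_threshold",
                                  "lactate_threshold"),
                         n_patients = 2500, ...) {
  name <- match.arg(name)
  p <- switch(
    name,
    paper_like = sim_params(n_patients = n_patients),
    null_confounded = {
      q <- sim_params(n_patients = n_patients)
      q$out_coefs["treated"] <- 0
      q
    },
    feedback = {
      q <- sim_params(n_patients = n_patients)
      q$out_coefs["treated"] <- log(0.7)
      q
    },
    no_confounding = {
      q <- sim_params(n_patients = n_patients)
      q$treat_coefs[c("sofa", "log_lactate", "map", "vaso", "serum_albumin")] <- 0
      q$feedback[] <- 0
      q
    },
    albumin_threshold = {
      q <- sim_params(
        n_patients = n_patients,
        alb_classes = list(frac = c(0.55, 0.45), mean = c(2.45, 2.78),
                           init_sd = c(0.12, 0.06), ar = c(0.85, 0.85),
                           innov_sd = c(0.05, 0.03)),
        effect_mod = list(variable = "serum_albumin",
                          breaks = c(-Inf, 2.7, Inf),
                          betas = c(log(0.4), log(6)))
      )
      q$out_coefs["treated"] <- log(0.4)
      q
    },
    lactate_threshold = {
      q <- sim_params(
        n_patients = n_patients,
        lac_classes = list(frac = c(0.6, 0.4), mean = c(log(2.9), log(2.05)),
                           init_sd = c(0.30, 0.05), ar = c(0.65, 0.8),
                           innov_sd = c(0.30, 0.035)),
        effect_mod = list(variable = "lactate",
                          breaks = c(-Inf, 2.2, Inf),
                          betas = c(log(6), log(0.3)))
      )
      q$out_coefs["treated"] <- log(0.3)
      q
    }
  )
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_class <- function(n, frac) {
  if (length(frac) == 1) rep(1L, n) else sample.int(length(frac), n, replace = TRUE, prob = frac)
}

#' Simulate a longitudinal ICU cohort with known causal truth
#'
#' Generates patients day by day: confounders from their kernels given
#' yesterday's state and treatment, treatment from the logistic model given
#' today's confounders and yesterday's treatment, then death in the day's
#' risk interval from the daily hazard given today's treatment and
#' confounders. Follow-up stops at death, discharge or the horizon. The
#' generating truth (parameters and conditional log HR) is stored in the
#' cohort's `meta$truth` and retrievable with [sim_truth()].
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical seed and parameters give an identical
#'   cohort.
#' @param regime `"natural"` (treatment from its model) or the forced regimes
#'   `"always"`/`"never"` used by the marginal oracle; the confounder kernels
#'   still respond to (forced) past treatment.
#' @param panel If `FALSE`, skip building the person-day panel and return
#'   only per-patient survival summaries (fast path for the oracle).
#' @return An `icu_cohort` (or, when `panel = FALSE`, a tibble with
#'   `patient_id`, `time`, `died`).
#' @examples
#' co <- simulate_cohort(sim_params(n_patients = 50), seed = 1)
#' co
#' @export
simulate_cohort <- function(params = sim_params(), seed = NULL,
                            regime = c("natural", "always", "never"),
                            panel = TRUE) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_patients
  H <- params$horizon
  tc <- params$treat_coefs
  oc <- params$out_coefs
  fb <- params$feedback
  if (n == 0) {
    empty_b <- tibble::tibble(patient_id = character())
    empty_d <- tibble::tibble(patient_id = character(), day = integer())
    return(icu_cohort(empty_b, empty_d, horizon = H,
                      meta = list(truth = list(params = params, seed = seed))))
  }

  id <- sprintf("p%05d", seq_len(n))
  age <- clamp(round(rnorm(n, 59, 10)), 18, 95)
  gender <- factor(ifelse(runif(n) < 0.64, "male", "female"))
  admission_type <- factor(sample(c("elective", "emergency", "observation",
                                    "surgical", "urgent"),
                                  n, replace = TRUE,
                                  prob = c(0.005, 0.63, 0.11, 0.02, 0.235)))
  ethnicity <- factor(sample(c("white", "black", "hispanic", "other"),
                             n, replace = TRUE, prob = c(0.62, 0.1, 0.08, 0.2)))
  infection_site <- factor(sample(c("respiratory", "gastrointestinal",
                                    "genitourinary", "other"),
                                  n, replace = TRUE,
                                  prob = c(0.18, 0.08, 0.08, 0.66)))
  weight <- clamp(rlnorm(n, log(81), 0.22), 35, 200)
  sofa0 <- clamp(round(rnorm(n, 4.5, 2.5)), 0, 24)
  meld <- clamp(round(rnorm(n, 20, 7)), 6, 40)
  sbp_flag <- runif(n) < 0.08
  aki_flag <- runif(n) < 0.65
  platelet0 <- clamp(rlnorm(n, log(82), 0.6), 5, 1000)
  bilirubin0 <- clamp(rlnorm(n, log(2.7), 0.9), 0.1, 60)

  acl <- params$alb_classes
  lcl <- params$lac_classes
  a_cls <- draw_class(n, acl$frac)
  l_cls <- draw_class(n, lcl$frac)
  baseline_albumin <- clamp(rnorm(n, acl$mean[a_cls], acl$init_sd[a_cls]), 1.2, 4.8)

  # state vectors (current day)
  sofa <- sofa0
  llac <- rnorm(n, lcl$mean[l_cls], lcl$init_sd[l_cls])
  map <- rnorm(n, 65, 9)
  alb <- baseline_albumin
  vaso <- pmax(0, 0.12 * (llac - log(2.2)) - 0.006 * (map - 65) + rnorm(n, 0, 0.06))
  uo <- rlnorm(n, log(1100), 0.6)
  pf <- clamp(rnorm(n, 190, 80), 40, 550)
  pf_ratio0 <- pf
  septic_shock0 <- vaso > 0 & exp(llac) > 2

  prev_A <- rep(0L, n)
  beta_A <- rep(unname(oc["treated"]), n)
  initiated <- rep(FALSE, n)
  active <- rep(TRUE, n)
  time <- rep(NA_integer_, n)
  died <- rep(FALSE, n)
  day_rows <- if (panel) vector("list", H) else NULL

  for (t in seq_len(H)) {
    idx <- which(active)
    if (length(idx) == 0) break
    if (t > 1) {
      A <- prev_A[idx]
      sofa[idx] <- clamp(round(5 + 0.75 * (sofa[idx] - 5) + fb[["sofa"]] * A +
                                 rnorm(length(idx), 0, 1.3)), 0, 24)
      mu_l <- lcl$mean[l_cls[idx]]
      llac[idx] <- mu_l + lcl$ar[l_cls[idx]] * (llac[idx] - mu_l) +
        fb[["log_lactate"]] * A + rnorm(length(idx), 0, lcl$innov_sd[l_cls[idx]])
      map[idx] <- 65 + 0.6 * (map[idx] - 65) + fb[["map"]] * A +
        rnorm(length(idx), 0, 6)
      mu_a <- acl$mean[a_cls[idx]]
      alb[idx] <- clamp(mu_a + acl$ar[a_cls[idx]] * (alb[idx] - mu_a) +
                          fb[["serum_albumin"]] * A +
                          rnorm(length(idx), 0, acl$innov_sd[a_cls[idx]]),
                        1.2, 4.8)
      vaso[idx] <- pmax(0, 0.45 * vaso[idx] + 0.12 * (llac[idx] - log(2.2)) -
                          0.005 * (map[idx] - 65) + rnorm(length(idx), 0, 0.05) - 0.02)
      uo[idx] <- exp(log(1100) + 0.5 * log(uo[idx] / 1100) -
                       0.06 * (sofa[idx] - 5) + rnorm(length(idx), 0, 0.45))
      pf[idx] <- clamp(190 + 0.7 * (pf[idx] - 190) - 5 * (sofa[idx] - 5) +
                         rnorm(length(idx), 0, 35), 40, 550)
    }

    eta_t <- tc[["intercept"]] + tc[["sofa"]] * (sofa[idx] - 5) +
      tc[["log_lactate"]] * (llac[idx] - log(2.2)) +
      tc[["map"]] * (map[idx] - 65) + tc[["vaso"]] * vaso[idx] +
      tc[["serum_albumin"]] * (alb[idx] - 2.8) + tc[["prev_treat"]] * prev_A[idx]
    A_t <- switch(regime,
                  natural = as.integer(runif(length(idx)) < plogis(eta_t)),
                  always = rep(1L, length(idx)),
                  never = rep(0L, length(idx)))

    if (!is.null(params$effect_mod)) {
      em <- params$effect_mod
      newly <- idx[A_t == 1L & !initiated[idx]]
      if (length(newly) > 0) {
        v <- switch(em$variable,
                    serum_albumin = alb[newly],
                    lactate = exp(llac[newly]),
                    map = map[newly],
                    vaso_nee = vaso[newly],
                    abort("unknown effect_mod variable", class = "albumsm_config_error"))
        beta_A[newly] <- em$betas[findInterval(v, em$breaks)]
        initiated[newly] <- TRUE
      }
    } else {
      initiated[idx[A_t == 1L]] <- TRUE
    }

    dose <- ifelse(A_t == 1L,
                   clamp(rlnorm(length(idx), params$dose_meanlog, params$dose_sdlog),
                         0.05, 3),
                   0)
    conc <- ifelse(A_t == 1L, ifelse(runif(length(idx)) < 0.7, 0.25, 0.05), NA_real_)

    eta_h <- oc[["log_lambda0"]] + beta_A[idx] * A_t +
      oc[["sofa"]] * (sofa[idx] - 5) +
      oc[["log_lactate"]] * (llac[idx] - log(2.2)) +
      oc[["map"]] * (map[idx] - 65) + oc[["vaso"]] * vaso[idx] +
      oc[["age"]] * (age[idx] - 59)
    p_death <- 1 - exp(-exp(eta_h))
    if (any(!is.finite(p_death))) {
      bad <- idx[which(!is.finite(p_death))[1]]
      abort(paste0("simulation error: non-finite hazard for patient ", id[bad],
                   " day ", t), class = "albumsm_sim_error")
    }
    ev <- runif(length(idx)) < p_death

    if (panel) {
      day_rows[[t]] <- tibble::tibble(
        patient_id = id[idx], day = t,
        sofa = sofa[idx], lactate = exp(llac[idx]), map = map[idx],
        vaso_nee = vaso[idx], urine_output = uo[idx], pf_ratio = pf[idx],
        serum_albumin = alb[idx], albumin_dose = dose, concentration = conc,
        treated = A_t == 1L, event = ev
      )
    }

    # exits: death ends follow-up; survivors may be discharged (noninformative)
    disc <- !ev & t >= 2 & runif(length(idx)) < params$discharge_rate
    gone <- ev | disc | t == H
    time[idx[gone]] <- t
    died[idx[gone]] <- ev[gone]
    active[idx[gone]] <- FALSE
    prev_A[idx] <- A_t
  }

  if (!panel) {
    return(tibble::tibble(patient_id = id, time = time, died = died))
  }

  days <- dplyr::bind_rows(day_rows)
  days$dose_stratum <- dose_stratum(days$albumin_dose)
  icu_admit_time <- round(runif(n, 0, 24 * 365), 1)
  extra_hosp <- rlnorm(n, log(72), 0.8)
  baselines <- tibble::tibble(
    patient_id = id, age = age, gender = gender,
    admission_type = admission_type, ethnicity = ethnicity,
    infection_site = infection_site, weight = weight,
    baseline_albumin = baseline_albumin, sofa0 = sofa0, meld = meld,
    sbp_flag = sbp_flag, aki_flag = aki_flag, septic_shock0 = septic_shock0,
    platelet0 = platelet0, pf_ratio0 = pf_ratio0, bilirubin0 = bilirubin0,
    icu_admit_time = icu_admit_time,
    hospital_admit_time = icu_admit_time - round(runif(n, 0, 48), 1),
    sepsis_onset_time = icu_admit_time + round(runif(n, -6, 12), 1),
    icu_los = time * 24,
    hospital_los = time * 24 + ifelse(died, 0, extra_hosp),
    icu_stay_index = 1L
  )
  icu_cohort(baselines, days, horizon = H,
             meta = list(truth = list(params = params, seed = seed, regime = regime,
                                      true_conditional_loghr = unname(oc["treated"]))))
}

#' Generating truth attached to a simulated cohort
#' @param cohort A simulated `icu_cohort`.
#' @return List with `params`, `seed`, `regime`, `true_conditional_loghr`, or
#'   `NULL` for non-simulated cohorts.
#' @export
sim_truth <- function(cohort) cohort$meta$truth

#' Large-sample oracle for the marginal causal hazard ratio
#'
#' Simulates the cohort under the two forced regimes "always treat" and
#' "never treat" (the confounder kernels still respond to past treatment) and
#' contrasts them with an unadjusted Cox model. The result is the marginal
#' hazard ratio the weighted estimator should recover; under
#' treatment-confounder feedback it differs from `exp(beta)` of the
#' conditional outcome model.
#'
#' @param params A [sim_params()] object.
#' @param n_oracle Patients per regime (default 200,000).
#' @param seed Integer seed.
#' @return Marginal hazard ratio (scalar).
#' @export
marginal_hr_oracle <- function(params, n_oracle = 2e5, seed = 1) {
  p <- params
  p$n_patients <- n_oracle
  a1 <- simulate_cohort(p, seed = seed, regime = "always", panel = FALSE)
  a0 <- simulate_cohort(p, seed = seed + 1, regime = "never", panel = FALSE)
  dat <- dplyr::bind_rows(dplyr::mutate(a1, arm = 1L), dplyr::mutate(a0, arm = 0L))
  fit <- survival::coxph(survival::Surv(time, died) ~ arm, data = dat,
                         ties = "breslow")
  unname(exp(coef(fit)))
}

#' Inject missing-at-random gaps into laboratory values
#'
#' Deletes values of the named day-level variables with probability depending
#' on the (always observed) ICU day, a missing-at-random mechanism. The
#' deleted truth is kept in `meta$missing_truth` so that imputation accuracy
#' can be scored against it.
#'
#' @param cohort An `icu_cohort`.
#' @param rates Named numeric vector of target missingness fractions in
#'   \[0, 1\] per variable.
#' @param seed Integer seed; the deletion mask is reproducible.
#' @param day_slope Log-odds change in the deletion probability per
#'   standardised day (the MAR dependence); 0 gives MCAR.
#' @return The cohort with `NA`s injected and the truth channel attached.
#' @export
inject_missingness <- function(cohort, rates, seed = NULL, day_slope = 0.3) {
  if (any(rates < 0 | rates > 1)) {
    abort("input error: missingness rates must lie in [0, 1]",
          class = "albumsm_input_error")
  }
  miss_vars <- setdiff(names(rates), names(cohort$days))
  if (length(miss_vars) > 0) {
    abort(paste0("schema error: no such day-level variable(s): ",
                 paste(miss_vars, collapse = ", ")),
          class = "albumsm_schema_error")
  }
  if (!is.null(seed)) set.seed(seed)
  days <- cohort$days
  z <- as.numeric(scale(days$day))
  if (all(is.na(z))) z <- rep(0, nrow(days))
  truth <- list()
  for (v in names(rates)) {
    r <- rates[[v]]
    p <- plogis(qlogis(r) + day_slope * z)
    if (r == 0) p <- rep(0, nrow(days))
    if (r == 1) p <- rep(1, nrow(days))
    hit <- runif(nrow(days)) < p
    hit <- hit & !is.na(days[[v]])
    if (any(hit)) {
      truth[[v]] <- tibble::tibble(patient_id = days$patient_id[hit],
                                   day = days$day[hit], variable = v,
                                   true_value = days[[v]][hit])
      days[[v]][hit] <- NA
    }
  }
  cohort$days <- days
  cohort$meta$missing_truth <- dplyr::bind_rows(truth)
  cohort
}
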