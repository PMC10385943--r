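# small handcrafted cohort used across cohort-level tests
tiny_cohort <- function() {
  baselines <- tibble::tibble(
    patient_id = c("p1", "p2"),
    age = c(60, 45), gender = factor(c("male", "female")),
    weight = c(80, 60), baseline_albumin = c(2.5, 3.1),
    icu_los = c(72, 48), hospital_los = c(120, 96),
    icu_admit_time = c(0, 0), sepsis_onset_time = c(-2, 6),
    icu_stay_index = c(1L, 1L), sbp_flag = c(FALSE, TRUE)
  )
  days <- tibble::tibble(
    patient_id = rep(c("p1", "p2"), each = 3),
    day = rep(1:3, 2),
    sofa = c(5, 6, 7, 3, 3, 2),
    lactate = c(2.5, 3.1, 2.8, 1.5, 1.8, 1.2),
    map = c(60, 55, 58, 70, 72, 75),
    vaso_nee = c(0.1, 0.2, 0.15, 0, 0, 0),
    serum_albumin = c(2.4, 2.6, 2.7, 3.1, 3.0, 3.2),
    albumin_dose = c(0, 0.5, 0.8, 0, 0, 0),
    treated = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    event = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  icu_cohort(baselines, days)
}

# fast small-scale scenario for pipeline-level unit tests
small_sim <- function(n = 250, scenario = "paper_like", seed = 42, ...) {
  simulate_cohort(sim_scenario(scenario, n_patients = n, ...), seed = seed)
}
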