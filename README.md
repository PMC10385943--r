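# albumsm

Causal survival analysis of **daily intravenous albumin administration in
septic patients with liver cirrhosis**, from longitudinal ICU person-day
data.

In this population, albumin is given day by day to the sickest patients —
the daily decision depends on SOFA score, serum lactate, MAP, vasopressor
dose, urine output, oxygenation and the serum albumin level itself — and
those same variables predict death. Past infusions also change the next
day's values of these variables (serum albumin rises, haemodynamics
improve), so the confounders are simultaneously *consequences of past
treatment* and *causes of future treatment*. Under this
treatment-confounder feedback, an ordinary time-varying Cox model adjusts
away part of the effect it is trying to estimate. `albumsm` implements the
standard remedy, the **marginal structural Cox model (MSCM)** estimated by
stabilized inverse probability of treatment weighting, for analysts working
with ICU electronic health record extracts (one row per patient per ICU
day) — plus a synthetic-cohort simulator with known causal ground truth so
every stage of the pipeline can be validated without access to restricted
clinical databases.

## The model

With daily exposure $A_t$ (any albumin vs none), baseline covariates $V$,
time-varying confounders $L_t$, the target marginal structural model is

$$\lambda_T(t \mid \bar a) = \lambda_0(t)\,e^{\beta a_t},$$

fitted by a weighted Cox partial likelihood in counting-process form, where
each person-day carries the cumulative stabilized weight

$$SW_t = \prod_{s\le t}
\frac{P(A_s = a_s \mid \bar A_{s-1}, s)}
     {P(A_s = a_s \mid \bar A_{s-1}, V, L_s, s)}$$

from two pooled logistic regressions. Variance is a robust sandwich
clustered on patient. On top of the overall effect the package provides
period-specific (Heaviside) hazard ratios by follow-up week, IPW-weighted
Kaplan–Meier curves, five-level dose-stratum weighting via multinomial
models, indication-defined sub-cohorts (clinical parameters on the day of
first infusion), iterative 0.1-unit threshold searches for serum albumin
and lactate initiation triggers, multiple imputation by weighted predictive
mean matching, and group-comparison / free-days reporting.

## Worked example

```r
library(albumsm)

co <- simulate_cohort(sim_scenario("paper_like", n_patients = 1200), seed = 7)
co
#> <icu_cohort> 1200 patients, 7285 person-days, horizon 28 d
#>   deaths: 356 (29.7%)
#>   ever treated: 520 (43.3%)

w   <- stabilized_weights(co)                  # numerator/denominator audit trail
rec <- build_counting_process(co, weights = w) # (start, stop] person-day records

fit_weighted_cox(rec)
#> <mscm_fit> weighted Cox model, 356 events / 1200 patients (breslow ties)
#>         term    hr conf.low conf.high p.value
#>  treatedTRUE 0.803    0.566      1.14   0.222

tidy(fit_weighted_cox(dplyr::mutate(rec, weight = 1)))  # crude, for contrast
#>         term   hr conf.low conf.high
#>  treatedTRUE 1.02    0.749       1.4

heaviside_fit(rec)$period_hrs
#>   period  days    hr conf.low conf.high estimable
#>  period1   1-7 0.719    0.479      1.08      TRUE
#>  period2  8-14 1.097    0.505      2.38      TRUE
#>  period3 15-21 1.967    0.507      7.64      TRUE
#>  period4 22-28    NA       NA        NA     FALSE
```

The generator's conditional hazard ratio here is 0.75, and treatment is
targeted at sicker patients: the crude estimate (1.02) is confounded toward
the null and beyond, while the weighted estimate (0.80) recovers the
protective effect. Late weeks have little exposed person-time at this
cohort size, so their Heaviside intervals widen or become non-estimable —
the same pattern expected in real 28-day ICU follow-up. `autoplot()`
methods exist for weight sets and weighted KM curves, `tidy()`/`glance()`
for fits, and `run_pipeline(pipeline_config(...))` executes the whole
study (filters, imputation, weights, MSCM, Heaviside, KM, sub-cohorts,
searches, subgroup and sensitivity analyses) reproducibly from a config
and seed.

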