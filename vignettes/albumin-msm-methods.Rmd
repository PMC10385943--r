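---
title: "Marginal structural models for daily albumin exposure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural models for daily albumin exposure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(albumsm)
```

## The estimation problem

Septic patients with liver cirrhosis receive intravenous albumin day by day,
and the decision to infuse on a given ICU day is driven by how sick the
patient looks that day: SOFA score, serum lactate, mean arterial pressure
(MAP), vasopressor requirement, urine output, oxygenation and the serum
albumin level itself. Those same variables predict death. Worse, albumin
given yesterday changes today's values of those variables (serum albumin
rises, haemodynamics improve), which in turn change today's treatment
decision. This is *treatment-confounder feedback*: the time-varying
confounders sit simultaneously on the causal pathway of past treatment and
on the assignment pathway of future treatment. Ordinary covariate
adjustment — putting $L_t$ into a time-varying Cox model — blocks part of
the effect being estimated and opens collider paths, so it cannot deliver
the causal contrast of interest.

The marginal structural Cox model (MSCM) addresses this by reweighting
rather than conditioning. Let $A_t \in \{0,1\}$ be any-dose albumin on day
$t$, $L_t$ the vector of time-varying confounders, $V$ the baseline
covariates, and $T$ the death time. The target model is

$$\lambda_T\big(t \mid \bar a\big) = \lambda_0(t)\, e^{\beta a_t},$$

the hazard at $t$ had the patient followed treatment history $\bar a$,
indexed by the current exposure. Each person-day receives the stabilized
inverse-probability-of-treatment weight

$$SW_t \;=\; \prod_{s \le t}
\frac{P(A_s = a_s \mid \bar A_{s-1}, s)}
     {P(A_s = a_s \mid \bar A_{s-1}, V, L_s, s)},$$

estimated by two pooled logistic regressions over the person-day panel. In
the weighted pseudo-population treatment is independent of the measured
confounders at every time, so a weighted Cox partial likelihood estimates
$\beta$ with a causal interpretation, under exchangeability given
$(V, L_t)$, positivity and correct model specification.

## Package data model and conventions

Everything operates on an `icu_cohort`: a baseline tibble (one row per
patient) plus a long person-day tibble (one row per patient per ICU day).
Conventions, fixed once and used everywhere:

* **Risk interval.** Day $t$'s covariates and treatment predict the event
  indicator of interval $(t, t+1]$; the counting-process records use
  `(t-1, t]` with the day-$t$ event flag, a pure relabelling that leaves
  the partial likelihood unchanged and avoids same-day reverse causation.
* **Censoring.** Administrative censoring at day 28; discharge alive ends
  follow-up at discharge (the alternative — assuming survival to day 28 —
  is not modelled). The simulator's discharge process is independent of
  covariates, so this censoring is noninformative by construction; no
  inverse-probability-of-censoring weights are used.
* **Units.** Serum albumin in g/dL throughout; infusion concentrations as
  fractions (25% = 0.25); vasopressors as norepinephrine-equivalent
  mcg/kg/min with an editable conversion table (`nee_conversion()`), since
  no standard reference fixes every factor.
* **Worst-of-day collapsing.** When a variable is charted repeatedly within
  a day, the value of greatest severity is kept (maximum for lactate, SOFA,
  vasopressor dose; minimum for MAP, P/F, urine output). The direction map
  is an overridable argument.
* **Dose.** Daily dose $= \sum_j \text{volume}_j \times
  \text{concentration}_j / \text{weight}$ (g/kg), with strata none,
  $(0, 0.5]$, $(0.5, 1.0]$, $(1.0, 1.5]$, $> 1.5$ — upper-closed
  boundaries.

## Weight models

The denominator model regresses the daily exposure on baseline covariates
(age, gender, admission type, ethnicity, infection site, baseline serum
albumin), the six time-varying confounders, time-varying serum albumin, the
previous day's treatment, and a 3-df natural spline in the ICU day (pooled
fits are far more stable than per-day models at late days with few rows).
Lactate enters on the log scale and urine output as log1p, matching their
skew.

Two deliberate choices deserve emphasis:

* **Time-varying serum albumin is in the denominator** even though the
  printed time-varying confounder set elsewhere often lists only SOFA,
  lactate, P/F, vasopressor dose, urine output and MAP. The serum albumin
  level is the very trigger of the prescription process (and of the
  indication analyses), so omitting it from the treatment model would
  leave the most important confounder unmodelled.
* **The numerator conditions on treatment history and time only**
  (default `~ 1` plus `prev_treat` and the day spline). If baseline
  covariates were put in the numerator, validity would require adjusting
  for them again in the weighted outcome model; keeping the numerator
  marginal lets the exposure-only weighted Cox model carry a marginal
  interpretation. Covariates can be added to the numerator (they must then
  be added to the outcome model), and doing so provably shrinks the
  variance of the log-weights — a property the test suite checks.

Fitted probabilities are clamped to $[10^{-6}, 1-10^{-6}]$ with a warning
counting the clamped rows (a positivity diagnostic). Cumulative weights are
winsorized by default at the pooled 1st/99th percentiles, using type-1
(inverse-ECDF) quantiles so a bound at $100k/n$ percent equals an order
statistic exactly; truncation can be switched off. Dose-strata weights use
`nnet::multinom` for the five-level exposure with the same
numerator/denominator structure.

As a diagnostic, the per-day mean of the cumulative stabilized weight
should sit near 1; the sampling band used in the tests is
$\pm 3/\sqrt{n_t}$ with $n_t$ the number of patients still at risk that
day, since that is the number of weights being averaged.

## Outcome models

`fit_weighted_cox()` maximizes the weight-incorporated partial likelihood
(weights multiply event terms and risk-set sums) via `survival::coxph`,
with Breslow tie handling by default (simple and robust under weights;
Efron available) and a robust sandwich variance clustered on patient —
mandatory, because the weighted likelihood is a pseudo-likelihood.
Confidence intervals are normal-theory on the log-HR scale. The test suite
holds this engine to an independent oracle: on small panels the fitted
coefficient must agree to $10^{-8}$ with direct maximization of the
explicitly written Breslow partial likelihood, and integer weights must
reproduce row-duplication fits exactly.

Period-specific effects use Heaviside step functions: the exposure is
interacted with indicators of days 1–7, 8–14, 15–21, 22–28 (cutpoints
7/14/21 for four consecutive weeks), giving each follow-up window its own
hazard ratio. A period with events under only one exposure level is
reported non-estimable rather than returning a divergent estimate.

The weighted Kaplan–Meier curve is the product-limit estimator with
weighted event and risk counts, $S(t) = \prod_{u\le t}(1 - d_w(u)/Y_w(u))$,
computed per current-exposure arm; it is hand-rolled (ten lines) and
cross-checked against `survival::survfit` in the tests.

For the multivariable model, `collinearity_filter()` removes one member of
each covariate pair with $|r|$ above 0.8 (priority = the order candidates
are listed), and `stepwise_select()` runs bidirectional stepwise selection
minimizing $-2\log L$ with the exposure always retained. A step is accepted
only if $-2\log L$ improves by more than 3.84 (the 1-df $\chi^2$ critical
value at 0.05); with a plain "lowest $-2\log L$" rule the full model always
wins, so a penalty is required to make selection meaningful. The
`extended_cox_timevarying()` robustness model is the same engine with unit
weights and direct adjustment for $L_t$ — valid only absent feedback, which
is exactly why it is a sensitivity analysis and not the primary estimator.

## Missing data

Variables with more than 60% missing values are excluded (a variable at
exactly 60% is retained — strict reading of "more than"); a mandatory
confounder above the threshold is a hard error rather than a silent drop.
Remaining gaps are multiply imputed by weighted predictive mean matching
within chained equations: for each target variable a linear model is fitted
on the observed rows, coefficients are drawn from their posterior (proper
imputation), and each gap receives the observed value of one of the
`k_donors = 5` donors with nearest predicted values, sampled with
probability inversely proportional to predictive distance — the "weighted"
element of weighted PMM. Defaults `m = 5`, 10 sweeps; predictors include
the other time-varying variables, the ICU day, the event indicator and a
few baseline anchors (all switchable). Observed cells are never altered and
imputed values always come from the observed support, both enforced by
tests. Fits across completed cohorts combine by Rubin's rules: pooled
coefficient = mean; total variance = within-mean $+ (1+1/m)\times$
between-variance; CIs on the log-HR scale. No MNAR sensitivity models are
attempted.

## Indication analyses and threshold searches

A sub-cohort compares treated patients whose trigger variable on the day of
their *first* infusion satisfies a rule (e.g. serum albumin in
$[2.5, 3.0)$ g/dL) against all never-treated patients; the comparator arm
is identical across rules, and the five prespecified albumin bins partition
the treated patients. Treated patients who initiated outside the rule are
*not* deleted: their pre-initiation person-days remain in the untreated
risk set and they are censored on the day of the off-rule infusion.
Deleting their whole history would condition the untreated risk set on a
future event (which treatment the patient eventually started); simulation
under a null effect shows that this selection biases the weighted contrast
protectively (median hazard ratio near 0.8 when the truth is 1), while the
censor-at-deviation construction is calibrated (median at 1.0). Follow-up
for both arms starts at ICU day 1, keeping the sub-cohort panel aligned
with the full-cohort person-day clock. Weights are re-estimated inside
each sub-cohort. Significance across a prespecified
rule family is Bonferroni-adjusted at $\alpha = 0.05/\text{family size}$.

The data-driven trigger searches move in 0.1-unit steps — serum albumin
upward from 2.5 g/dL with rules "first-infusion albumin $< c$", lactate
downward from 3.0 mmol/L with rules "first-infusion lactate $\ge c$" — and
qualify a threshold when the upper 95% bound of the sub-cohort hazard ratio
is below 1 (the point-estimate alternative is weaker and not used). The
search is sequential: a single failing threshold stops it, and the returned
trigger is the last qualifying one. This strict reading keeps the
false-positive behaviour of the whole search at the single-test level,
which matters because nested arms make the per-threshold tests strongly
dependent.

## The synthetic cohort generator

`simulate_cohort()` draws baselines, then for each day: confounders from
linear-Gaussian AR(1) kernels on transformed scales (log lactate, bounded
serum albumin, integer-clamped SOFA), treatment from a logistic model in
the current confounders and yesterday's treatment, and death in the day's
interval from a complementary-log-log hazard, so the treatment coefficient
is a conditional log hazard ratio. Yesterday's treatment feeds into today's
confounders — mainly through serum albumin (which drives treatment but not
the hazard) with small effects on SOFA, lactate and MAP — producing genuine
treatment-confounder feedback while keeping the single-exposure marginal
model a good description of the regime contrast. The default preset aims at
the magnitudes of a septic-cirrhosis ICU population (about 28% in-ICU
28-day mortality, just under half of patients ever treated, median lactate
near 2.2 mmol/L, mean stay around six days); these are realism targets
only, never test assertions.

`marginal_hr_oracle()` supplies the causal ground truth: it simulates the
same generating process under the forced regimes "always treat" and "never
treat" (kernels still responding to treatment) and contrasts them with an
unadjusted Cox model at $n = 200{,}000$ per arm. This brute-force regime
simulation is what the weighted estimator is asked to recover.

The two threshold-recovery scenarios define effect modification by the
value of the trigger variable on each patient's first treated day: benefit
(HR 0.4 for albumin, 0.3 for lactate) inside the designed band, an adverse
effect (HR 6) in the adjacent band beyond the designed trigger. Because a
nested-arm search can only stop where the pooled sub-cohort estimate loses
significance, the scenarios use a two-class trajectory mixture that places
a sizeable share of initiations immediately beyond the trigger; without
that concentration no sequential search — whatever the implementation —
could localize the boundary at desk scale. The adverse band has a clinical
reading (fluid overload from albumin given without hypoalbuminaemia or
hypoperfusion) but its size is chosen for identifiability, not realism.

What the generator does *not* emulate: hour-level physiology, informative
discharge, competing post-ICU mortality, measurement error, MNAR
missingness, or between-centre heterogeneity. Passing the test suite
therefore demonstrates that the estimation machinery is correct under its
stated assumptions — not that those assumptions hold in any particular EHR
cohort.

## Numerical choices and problem sizes

* Logistic fits: `stats::glm`; separation surfaces as a clamping warning.
* Cox fits: convergence tolerance $10^{-12}$, at most 50 iterations;
  monotone likelihood (|coef| > 15) raises an error naming the term; in
  the Heaviside fit the offending period is dropped and flagged instead.
* Determinism: every stochastic stage takes an explicit seed;
  `run_pipeline()` derives stage seeds from the config seed, and identical
  config + seed reproduces the result bundle byte for byte.
* Test scales: the calibration studies use 500 null cohorts of 1,000
  patients; recovery uses 200 cohorts of 2,000 against an oracle at
  200,000 per regime; the threshold searches use 50 replicates of 4,000;
  the imputation accuracy check uses a panel of about 5,000 person-days
  with 30% lactate missingness. The period-specific consistency study uses
  an extended-stay variant (5%/day discharge instead of 15%) because with
  the default turnover week 4 holds almost no exposed person-time and its
  hazard ratio is not identifiable at desk scale — the very wide week-4
  intervals typical of 28-day ICU analyses reflect the same thinness. These sizes put Monte-Carlo error well
  inside the tolerances being asserted while keeping the full suite a
  desk-scale computation.

## Known limitations

* Censoring weights for discharge are not implemented; with informative
  discharge the estimates would be biased accordingly.
* The interaction test in `subgroup_analysis()` is designed for two-level
  subgroups (multi-level factors are coded ordinally in the product term).
* The MSM is indexed by current exposure only; cumulative-dose or
  duration-response marginal models are out of scope.
* PMM assumes enough observed donors per variable; very high missingness
  combined with small cohorts degrades the donor pool before the 60% rule
  triggers.
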