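# Independent brute-force oracle for the weighted Cox partial likelihood
# (Breslow ties): the log partial likelihood is written out directly from its
# definition and maximized numerically, with no reference to the package's
# fitting path.

brute_breslow_loglik <- function(beta, records, xcols) {
  x <- as.matrix(records[xcols])
  eta <- drop(x %*% beta)
  w <- records$weight
  ll <- 0
  for (t in sort(unique(records$stop[records$event]))) {
    dead <- records$event & records$stop == t
    risk <- records$start < t & records$stop >= t
    ll <- ll + sum(w[dead] * eta[dead]) -
      sum(w[dead]) * log(sum(w[risk] * exp(eta[risk])))
  }
  ll
}

# hand-derived score of the Breslow log partial likelihood (single covariate)
brute_breslow_score <- function(beta, records, xcol) {
  x <- records[[xcol]]
  w <- records$weight
  e <- w * exp(beta * x)
  s <- 0
  for (t in sort(unique(records$stop[records$event]))) {
    dead <- records$event & records$stop == t
    risk <- records$start < t & records$stop >= t
    s <- s + sum(w[dead] * x[dead]) -
      sum(w[dead]) * sum(e[risk] * x[risk]) / sum(e[risk])
  }
  s
}

brute_cox_fit_1d <- function(records, xcol, lower = -10, upper = 10) {
  peak <- optimize(function(b) brute_breslow_loglik(b, records, xcol),
                   interval = c(lower, upper), maximum = TRUE, tol = 1e-8)$maximum
  if (abs(peak) > 8) return(peak)  # near-boundary: report, callers screen it out
  uniroot(function(b) brute_breslow_score(b, records, xcol),
          interval = c(peak - 1, peak + 1), extendInt = "downX",
          tol = 1e-13)$root
}

# random small counting-process panel: one record per subject, binary
# covariate, continuous event times (no ties unless forced)
random_small_panel <- function(n_subj, seed) {
  set.seed(seed)
  repeat {
    x <- rbinom(n_subj, 1, 0.5)
    time <- round(rexp(n_subj, rate = exp(0.5 * x) / 4), 3) + 0.001
    event <- runif(n_subj) < 0.8
    rec <- tibble::tibble(
      patient_id = sprintf("s%02d", seq_len(n_subj)),
      start = 0, stop = time, event = event, treated = x, weight = 1
    )
    # need both exposure levels, events in each exposure group, and an
    # interior partial-likelihood maximum (checked with the oracle itself,
    # so the screen stays independent of the fitting path)
    if (length(unique(x)) == 2 && sum(event) >= 2 &&
        sum(event & x == 1) >= 1 && sum(event & x == 0) >= 1 &&
        abs(brute_cox_fit_1d(rec, "treated")) < 5) {
      return(rec)
    }
    seed <- seed + 10000
    set.seed(seed)
  }
}
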