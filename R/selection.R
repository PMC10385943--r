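#' Remove highly correlated covariates
#'
#' Computes the pairwise Pearson correlation of candidate covariates on the
#' person-day panel and, for every pair exceeding the threshold, drops the
#' member that sits lower in the priority order (by default, the order the
#' candidates were given), greedily from the strongest correlation down.
#'
#' @param data Data frame (typically `as_tibble(cohort)`).
#' @param candidates Character vector of numeric (or logical) columns.
#' @param r_threshold Absolute correlation above which a pair is collinear
#'   (default 0.8).
#' @param priority Character vector ranking candidates from most to least
#'   preferred; defaults to `candidates`.
#' @return List with `retained`, `dropped` (tibble of term, partner, r) and
#'   the full `cor_matrix`.
#' @export
collinearity_filter <- function(data, candidates, r_threshold = 0.8,
                                priority = candidates) {
  x <- as.data.frame(lapply(data[candidates], as.numeric))
  cm <- cor(x, use = "pairwise.complete.obs")
  dropped <- tibble::tibble(term = character(), partner = character(), r = numeric())
  active <- candidates
  pairs <- which(upper.tri(cm) & abs(cm) > r_threshold, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    ord <- order(-abs(cm[pairs]))
    for (k in ord) {
      a <- candidates[pairs[k, 1]]
      b <- candidates[pairs[k, 2]]
      if (!(a %in% active) || !(b %in% active)) next
      loser <- if (match(a, priority) <= match(b, priority)) b else a
      winner <- setdiff(c(a, b), loser)
      dropped <- dplyr::bind_rows(dropped,
                                  tibble::tibble(term = loser, partner = winner,
                                                 r = cm[pairs[k, 1], pairs[k, 2]]))
      active <- setdiff(active, loser)
    }
  }
  list(retained = active, dropped = dropped, cor_matrix = cm)
}

#' Stepwise covariate selection by -2 log partial likelihood
#'
#' Bidirectional stepwise selection on the weighted Cox model: at each step
#' the single addition or removal that most improves -2 log L is taken,
#' provided the improvement exceeds `penalty` (default 3.84, the 1-df
#' chi-square critical value at 0.05, which prevents degenerate full-model
#' selection). The exposure term is always retained. The trace records the
#' accepted steps, along which -2 log L is non-increasing by construction.
#'
#' @param records Counting-process tibble.
#' @param candidates Character vector of candidate covariate terms (should
#'   already have passed [collinearity_filter()]).
#' @param exposure Exposure term, always kept.
#' @param penalty Minimum -2 log L improvement to accept a step.
#' @param ties Tie method.
#' @return List with `selected` terms, the final `fit` (an `mscm_fit`) and
#'   the selection `trace` tibble.
#' @export
stepwise_select <- function(records, candidates, exposure = "treated",
                            penalty = 3.84, ties = "breslow") {
  current <- character()
  m2l <- function(covs) {
    fit_weighted_cox(records, terms = c(exposure, covs), exposure = exposure,
                     ties = ties)$minus2logl
  }
  best <- m2l(current)
  trace <- tibble::tibble(step = 0L, action = "start", term = NA_character_,
                          minus2logl = best)
  repeat {
    moves <- dplyr::bind_rows(
      purrr::map(setdiff(candidates, current),
                 ~ tibble::tibble(action = "add", term = .x)),
      purrr::map(current, ~ tibble::tibble(action = "drop", term = .x))
    )
    if (nrow(moves) == 0) break
    moves$minus2logl <- purrr::map_dbl(seq_len(nrow(moves)), function(i) {
      covs <- if (moves$action[i] == "add") c(current, moves$term[i]) else
        setdiff(current, moves$term[i])
      tryCatch(m2l(covs), error = function(e) Inf)
    })
    i <- which.min(moves$minus2logl)
    if (best - moves$minus2logl[i] <= penalty) break
    best <- moves$minus2logl[i]
    current <- if (moves$action[i] == "add") c(current, moves$term[i]) else
      setdiff(current, moves$term[i])
    trace <- dplyr::bind_rows(trace,
                              tibble::tibble(step = max(trace$step) + 1L,
                                             action = moves$action[i],
                                             term = moves$term[i],
                                             minus2logl = best))
  }
  list(selected = current,
       fit = fit_weighted_cox(records, terms = c(exposure, current),
                              exposure = exposure, ties = ties),
       trace = trace)
}
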