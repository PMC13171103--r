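#' Label early/late behavioral states
#'
#' The late (rule-following) state is the maximal terminal run of consecutive
#' correct trials; everything before it is the early (trial-and-error) state.
#' The switch point is the first late trial.
#'
#' @param trials trial table with an `outcome` column
#'   (`"correct"`/`"incorrect"`).
#' @return List of class `"state_labeling"`: `state` (factor-ish character
#'   vector, `"early"`/`"late"`), `switch_point` (1-based index of the first
#'   late trial), `n_trials`.
#' @export
label_states <- function(trials) {
  outcomes <- trials$outcome == "correct"
  n <- length(outcomes)
  if (n == 0) stop("empty trial table")
  if (!outcomes[n]) stop("sequence has no terminal correct run (last trial incorrect)")
  r <- rle(outcomes)
  run_len <- r$lengths[length(r$lengths)]
  switch_point <- n - run_len + 1L
  state <- rep("early", n)
  state[switch_point:n] <- "late"
  structure(list(state = state, switch_point = switch_point, n_trials = n),
            class = "state_labeling")
}

#' Trials to criterion
#'
#' The criterion trial is the first at which the animal has both dug
#' correctly six times consecutively and accumulated at least two correct
#' rejections. Rejections are counted cumulatively across the stage, not only
#' within the criterion run.
#'
#' @param trials trial table with `outcome` and `correct_rejection`.
#' @return Integer trial index, or `NA_integer_` if the criterion is never
#'   reached.
#' @export
trials_to_criterion <- function(trials) {
  outcomes <- trials$outcome == "correct"
  n <- length(outcomes)
  if (n == 0) stop("empty trial table")
  cum_cr <- cumsum(trials$correct_rejection)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (outcomes[i]) run + 1L else 0L
    if (run >= 6L && cum_cr[i] >= 2L) return(i)
  }
  NA_integer_
}
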