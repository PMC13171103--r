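#' Per-trial pre-choice means
#'
#' Collapses an aligned tensor to a trials-by-neurons matrix by averaging
#' over all bins of the window, the summary every single-cell contrast and
#' both decoders operate on.
#'
#' @param tensor an `aligned_tensor` from [extract_window()].
#' @return Matrix `[n_trials x n_neurons]`.
#' @export
trial_mean_prechoice <- function(tensor) {
  apply(tensor, c(1, 2), mean)
}

#' ROC area under the curve
#'
#' `AUC = P(value_pos > value_neg) + 0.5 P(tie)`, computed by the rank-sum
#' formula (identical to exhaustive pair counting). Returns `NA` when either
#' class has fewer than two trials (the neuron is unclassifiable for that
#' contrast rather than an error).
#'
#' @param values per-trial scalars.
#' @param labels logical (or 0/1) per-trial class labels; `TRUE` is the
#'   positive class.
#' @return AUC in `[0, 1]`, or `NA_real_`.
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 < 2 || n0 < 2) return(NA_real_)
  r <- rank(values)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Label-permutation p-value for an ROC contrast
#'
#' Two-sided add-one permutation test on `|AUC - 0.5|`:
#' `p = (1 + #permuted deviations >= observed) / (n_perm + 1)`, with label
#' permutations drawn uniformly.
#'
#' @param values per-trial scalars.
#' @param labels logical per-trial labels.
#' @param n_perm number of permutations (>= 100).
#' @return p-value in `(0, 1]`, or `NA_real_` if the contrast is
#'   unclassifiable.
#' @export
permutation_pvalue <- function(values, labels, n_perm = 1000) {
  stopifnot(n_perm >= 100)
  labels <- as.logical(labels)
  obs <- roc_auc(values, labels)
  if (is.na(obs)) return(NA_real_)
  n <- length(values)
  n1 <- sum(labels)
  r <- rank(values)
  offset <- n1 * (n1 + 1) / 2
  denom <- n1 * (n - n1)
  dev_obs <- abs(obs - 0.5)
  dev_perm <- vapply(seq_len(n_perm), function(b) {
    abs((sum(r[sample.int(n, n1)]) - offset) / denom - 0.5)
  }, numeric(1))
  (1 + sum(dev_perm >= dev_obs - 1e-12)) / (n_perm + 1)
}

#' Classify every neuron's pre-choice tuning in a session
#'
#' Three contrasts on the (-5, 0) s pre-choice window means: *switch*
#' compares early vs late trials, *history* compares trials preceded by a
#' correct vs an incorrect trial (trial 1 dropped), *choice* compares trials
#' by their upcoming outcome. Significance per contrast is the two-sided
#' label-permutation test on |AUC - 0.5|; a neuron is responsive at
#' `p < alpha`. No multiple-testing correction is applied across neurons or
#' contrasts (responsive fractions are reported at raw alpha).
#'
#' @param session a `ca_session`.
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations per contrast (default 1000).
#' @param seed optional seed for the permutation draws.
#' @return A `data.frame` of class `"tuning_result"`: per neuron AUC and p
#'   for each contrast, `responsive_*` flags, `mixed` (at least two flags)
#'   and `responsive_any`.
#' @export
classify_session <- function(session, alpha = 0.05, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labeling <- label_states(session$trials)
  Fz <- zscore_per_neuron(session_fluor(session))
  tens <- extract_window(Fz, session$trials, c(-5, 0))
  M <- trial_mean_prechoice(tens)  # trials x neurons
  prev_correct <- c(NA, utils::head(session$trials$outcome, -1) == "correct")
  contrasts <- list(
    switch = labeling$state == "late",
    history = prev_correct,
    choice = session$trials$outcome == "correct"
  )
  ids <- rownames(session$traces) %||% sprintf("n%03d", seq_len(ncol(M)))
  out <- data.frame(neuron_id = ids, stringsAsFactors = FALSE)
  for (cn in names(contrasts)) {
    lab <- contrasts[[cn]]
    keep <- !is.na(lab)
    auc <- p <- rep(NA_real_, ncol(M))
    for (j in seq_len(ncol(M))) {
      auc[j] <- roc_auc(M[keep, j], lab[keep])
      if (!is.na(auc[j])) p[j] <- permutation_pvalue(M[keep, j], lab[keep], n_perm)
    }
    out[[paste0("auc_", cn)]] <- auc
    out[[paste0("p_", cn)]] <- p
    out[[paste0("responsive_", cn)]] <- !is.na(p) & p < alpha
  }
  flags <- as.matrix(out[, paste0("responsive_", names(contrasts))])
  out$mixed <- rowSums(flags) >= 2
  out$responsive_any <- rowSums(flags) >= 1
  class(out) <- c("tuning_result", "data.frame")
  out
}

#' Responsive-fraction count table across groups
#'
#' Pools tuning results across sessions within each group and tabulates
#' responsive vs non-responsive counts per task variable, plus the overall
#' responsive fraction and the mixed-tuning fraction among responsive
#' neurons.
#'
#' @param results_by_group named list (`control`, `test`) of
#'   `tuning_result` data frames (pooled or per-session; per-session lists
#'   are row-bound).
#' @return A `data.frame`: variable, per-group responsive counts, totals and
#'   integer display percentages.
#' @export
fraction_table <- function(results_by_group) {
  pool <- lapply(results_by_group, function(x) {
    if (is.data.frame(x)) x else do.call(rbind, x)
  })
  stopifnot(all(vapply(pool, nrow, 1L) >= 1))
  vars <- c("choice", "history", "switch", "any")
  rows <- lapply(vars, function(v) {
    col <- if (v == "any") "responsive_any" else paste0("responsive_", v)
    cnt <- vapply(pool, function(df) sum(df[[col]], na.rm = TRUE), 1L)
    tot <- vapply(pool, nrow, 1L)
    data.frame(variable = v, n_responsive_control = cnt[["control"]],
               n_total_control = tot[["control"]],
               n_responsive_test = cnt[["test"]], n_total_test = tot[["test"]])
  })
  mix <- lapply(pool, function(df) {
    resp <- df[df$responsive_any, , drop = FALSE]
    c(sum(resp$mixed), nrow(resp))
  })
  rows[[length(rows) + 1L]] <- data.frame(
    variable = "mixed", n_responsive_control = mix$control[1],
    n_total_control = mix$control[2],
    n_responsive_test = mix$test[1], n_total_test = mix$test[2])
  tab <- do.call(rbind, rows)
  tab$pct_control <- round(100 * tab$n_responsive_control / tab$n_total_control)
  tab$pct_test <- round(100 * tab$n_responsive_test / tab$n_total_test)
  tab
}

#' Pearson chi-squared test on a 2x2 count table
#'
#' Degrees of freedom 1, no continuity correction; upper-tail p from the
#' chi-squared distribution.
#'
#' @param tab 2x2 matrix: rows = groups, columns = (responsive,
#'   non-responsive).
#' @return List with `statistic`, `p`, `df = 1`.
#' @export
chi_squared_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("negative cell count")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p = ct$p.value, df = 1L)
}
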