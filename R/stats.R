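#' Two-group comparison following the study's decision rule
#'
#' Two-tailed Wilcoxon rank-sum (normal approximation with tie correction,
#' reporting the rank sum of the first sample) when both samples have more
#' than 7 observations; otherwise a two-tailed pooled-variance two-sample
#' t-test with `n1 + n2 - 2` degrees of freedom. The rule keys on
#' `min(n1, n2)`.
#'
#' @param x,y numeric samples.
#' @return List of class `"group_test"`: `statistic`, `p`, `test_name`
#'   (`"ranksum"` or `"pooled_t"`), `df` (t only), `n1`, `n2`.
#' @export
compare_groups <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  if (n1 == 1 && n2 == 1) stop("cannot compare two singletons (no variance)")
  if (min(n1, n2) > 7) {
    N <- n1 + n2
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n1)])
    mu <- n1 * (N + 1) / 2
    ties <- table(c(x, y))
    tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_corr)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (W - mu) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    structure(list(statistic = W, p = min(p, 1), test_name = "ranksum",
                   df = NA_real_, n1 = n1, n2 = n2), class = "group_test")
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df)
    structure(list(statistic = tstat, p = p, test_name = "pooled_t",
                   df = df, n1 = n1, n2 = n2), class = "group_test")
  }
}
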