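#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for one E-step.
// logdens: T x K log emission densities; pi: K initial probs; A: K x K
// row-stochastic transitions. Returns gamma (T x K posteriors), xi_sum
// (K x K expected transition counts) and the sequence log-likelihood.
// Per-row shifting of logdens keeps the scaled recursion finite for any T.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logdens, NumericVector pi,
                          NumericMatrix A) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix dens(T, K);
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logdens(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logdens(t, k));
    shift[t] = m;
    for (int k = 0; k < K; ++k) dens(t, k) = std::exp(logdens(t, k) - m);
  }
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  double loglik = 0.0;
  // forward
  for (int k = 0; k < K; ++k) alpha(0, k) = pi[k] * dens(0, k);
  c[0] = 0.0;
  for (int k = 0; k < K; ++k) c[0] += alpha(0, k);
  if (c[0] <= 0) stop("forward pass underflow at t=1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= c[0];
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, j);
      alpha(t, j) = s * dens(t, j);
      ct += alpha(t, j);
    }
    if (ct <= 0) stop("forward pass underflow at t=", t + 1);
    for (int j = 0; j < K; ++j) alpha(t, j) /= ct;
    c[t] = ct;
  }
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + shift[t];
  // backward (scaled)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j)
        s += A(i, j) * dens(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / c[t + 1];
    }
  }
  // posteriors and transition expectations
  NumericMatrix xi_sum(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t + 1 < T; ++t) {
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi_sum(i, j) += alpha(t, i) * A(i, j) * dens(t + 1, j) *
                        beta(t + 1, j) / c[t + 1];
  }
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = loglik);
}

// Exact max-probability path in log space; ties broken toward the lower
// state index (strict > when updating, first-max argmax at the end).
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logdens, NumericVector logpi,
                          NumericMatrix logA) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logdens(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based states
}
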