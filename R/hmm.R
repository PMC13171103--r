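#' Pre-choice population means per trial
#'
#' Mean z-scored activity of each neuron over the 5 s window preceding each
#' choice: the trials x neurons matrix both decoders build their features
#' from. (Averaging the 50 ms-binned window collapses to this scalar mean.)
#'
#' @param session a `ca_session`.
#' @return Matrix `[n_trials x n_neurons]`.
#' @export
prechoice_means <- function(session) {
  Fz <- zscore_per_neuron(session_fluor(session))
  tens <- extract_window(Fz, session$trials, c(-5, 0))
  trial_mean_prechoice(tens)
}

# PCA scores of a trials x neurons matrix (centered, no scaling).
pca_scores <- function(M, n_components) {
  if (n_components > ncol(M)) {
    stop("n_components (", n_components, ") exceeds neuron count (", ncol(M), ")")
  }
  Xc <- sweep(M, 2, colMeans(M))
  tot <- sum(Xc^2)
  if (tot < 1e-12) stop("degenerate session: constant activity across trials")
  sv <- La.svd(Xc, nu = 0, nv = min(dim(Xc)))
  Xc %*% t(sv$vt[seq_len(n_components), , drop = FALSE])
}

#' Low-dimensional per-trial features for state decoding
#'
#' Applies PCA across trials to the pre-choice mean matrix (optionally on a
#' neuron subset) and retains the leading components, in chronological trial
#' order.
#'
#' @param session a `ca_session`.
#' @param n_components retained PCs (default 3).
#' @param neurons optional neuron index subset.
#' @return Matrix `[n_trials x n_components]`.
#' @export
trial_features <- function(session, n_components = 3, neurons = NULL) {
  M <- prechoice_means(session)
  if (!is.null(neurons)) M <- M[, neurons, drop = FALSE]
  pca_scores(M, n_components)
}

#' K-means initialization of a Gaussian HMM
#'
#' Lloyd's algorithm with `nstart` restarts (best within-cluster sum of
#' squares) groups trials into `k` clusters; emission means/variances,
#' transition counts (add-one smoothed) and initial probabilities are seeded
#' from the assignment.
#'
#' @param features trials x dims matrix.
#' @param k number of states (default 2).
#' @param nstart random restarts (default 10).
#' @param var_floor lower bound on emission variances.
#' @return List: `assignment`, `initial`, `transition`, `means`, `vars`.
#' @export
kmeans_init <- function(features, k = 2, nstart = 10, var_floor = 1e-6) {
  features <- as.matrix(features)
  T_len <- nrow(features)
  stopifnot(T_len >= 2 * k)
  if (k == 1) {
    assign <- rep(1L, T_len)
  } else {
    km <- NULL
    for (attempt in seq_len(20)) {
      km <- tryCatch(
        stats::kmeans(features, centers = k, nstart = nstart, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(stats::kmeans(features, centers = k, nstart = nstart,
                                         iter.max = 200, algorithm = "Lloyd"))
        })
      if (!is.null(km) && all(km$size > 0)) break
      km <- NULL
    }
    if (is.null(km)) stop("kmeans_init: empty cluster after 20 re-seeding attempts")
    assign <- km$cluster
  }
  init_from_assignment(features, assign, k, var_floor)
}

#' Contiguous changepoint initialization of a 2-state Gaussian HMM
#'
#' Scans all single-changepoint partitions of the chronological sequence and
#' keeps the one with minimal within-segment sum of squares; emission and
#' transition parameters are seeded from that split exactly as in
#' [kmeans_init()]. An unsupervised alternative initialization reflecting
#' the single-switch structure the model is meant to capture.
#'
#' @param features trials x dims matrix in chronological order.
#' @param min_segment smallest allowed segment length (default 2).
#' @param var_floor lower bound on emission variances.
#' @return Same structure as [kmeans_init()].
#' @export
changepoint_init <- function(features, min_segment = 2, var_floor = 1e-6) {
  X <- as.matrix(features)
  T_len <- nrow(X)
  stopifnot(T_len >= 2 * min_segment)
  cs <- apply(X, 2, cumsum)
  cs2 <- apply(X^2, 2, cumsum)
  tot <- cs[T_len, ]; tot2 <- cs2[T_len, ]
  best <- Inf; best_t <- min_segment + 1L
  for (t in (min_segment + 1L):(T_len - min_segment + 1L)) {
    n1 <- t - 1L; n2 <- T_len - n1
    s1 <- cs[n1, ]; s12 <- cs2[n1, ]
    wcss <- sum(s12 - s1^2 / n1) + sum((tot2 - s12) - (tot - s1)^2 / n2)
    if (wcss < best) { best <- wcss; best_t <- t }
  }
  assign <- rep(1L, T_len)
  assign[best_t:T_len] <- 2L
  init_from_assignment(X, assign, 2L, var_floor)
}

# emission/transition/initial parameters from a hard state assignment
init_from_assignment <- function(X, assign, k, var_floor) {
  d <- ncol(X)
  means <- matrix(0, k, d)
  vars <- matrix(1, k, d)
  for (s in seq_len(k)) {
    xs <- X[assign == s, , drop = FALSE]
    means[s, ] <- colMeans(xs)
    v <- apply(xs, 2, function(col) mean((col - mean(col))^2))
    vars[s, ] <- pmax(v, var_floor)
  }
  trans <- matrix(1, k, k)  # add-one smoothing
  T_len <- length(assign)
  if (T_len > 1) {
    for (t in seq_len(T_len - 1)) {
      trans[assign[t], assign[t + 1]] <- trans[assign[t], assign[t + 1]] + 1
    }
  }
  trans <- trans / rowSums(trans)
  list(assignment = assign, initial = tabulate(assign, k) / T_len,
       transition = trans, means = means, vars = vars)
}

# T x K log densities under diagonal Gaussians
gauss_logdens <- function(X, means, vars) {
  K <- nrow(means)
  out <- matrix(0, nrow(X), K)
  for (s in seq_len(K)) {
    out[, s] <- -0.5 * rowSums(sweep(sweep(X, 2, means[s, ])^2, 2, vars[s, ], "/")) -
      0.5 * sum(log(2 * pi * vars[s, ]))
  }
  out
}

#' Fit a diagonal-Gaussian HMM by Baum-Welch
#'
#' Expectation-maximization on a chronological feature sequence with scaled
#' forward-backward recursions (no underflow for any practical length).
#' Stops when the log-likelihood gain falls below `tol` or at `max_iter`.
#' The log-likelihood trace is non-decreasing (within numerical tolerance)
#' by the EM monotonicity property.
#'
#' @param features trials x dims matrix (chronological order).
#' @param init initialization from [kmeans_init()].
#' @param max_iter maximum EM iterations (default 100).
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param var_floor lower bound on emission variances (default 1e-6).
#' @return List of class `"hmm_model"`: `initial`, `transition`, `means`,
#'   `vars`, `log_likelihood_trace`, `converged`.
#' @export
fit_baum_welch <- function(features, init, max_iter = 100, tol = 1e-4,
                           var_floor = 1e-6) {
  X <- as.matrix(features)
  K <- nrow(init$means)
  pi0 <- init$initial
  # keep initial distribution strictly positive so either start state is reachable
  pi0 <- (pi0 + 1e-3) / sum(pi0 + 1e-3)
  A <- init$transition
  means <- init$means
  vars <- pmax(init$vars, var_floor)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- gauss_logdens(X, means, vars)
    e <- hmm_forward_backward(ld, pi0, A)
    if (!is.finite(e$loglik)) stop("non-finite likelihood at EM iteration ", it)
    ll_trace <- c(ll_trace, e$loglik)
    if (it > 1 && (ll_trace[it] - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    g <- e$gamma
    pi0 <- pmax(g[1, ], 1e-12)
    pi0 <- pi0 / sum(pi0)
    A <- e$xi_sum / pmax(rowSums(e$xi_sum), 1e-300)
    wsum <- colSums(g)
    for (s in seq_len(K)) {
      w <- g[, s] / wsum[s]
      means[s, ] <- colSums(X * w)
      vars[s, ] <- pmax(colSums(sweep(X, 2, means[s, ])^2 * w), var_floor)
    }
  }
  structure(list(initial = pi0, transition = A, means = means, vars = vars,
                 log_likelihood_trace = ll_trace, converged = converged),
            class = "hmm_model")
}

#' Viterbi decoding
#'
#' Exact maximum-probability hidden-state path in log space; ties break
#' toward the lower state index.
#'
#' @param model an `hmm_model` (or any list with `initial`, `transition`,
#'   `means`, `vars`).
#' @param features trials x dims matrix.
#' @return Integer state sequence (1-based).
#' @export
viterbi <- function(model, features) {
  X <- as.matrix(features)
  ld <- gauss_logdens(X, model$means, model$vars)
  hmm_viterbi(ld, log(pmax(model$initial, 1e-300)),
              log(pmax(model$transition, 1e-300)))
}

#' Posterior state probabilities (forward-backward)
#'
#' @inheritParams viterbi
#' @return List with `gamma` (T x K posteriors, rows sum to 1) and `loglik`.
#' @export
posterior_states <- function(model, features) {
  X <- as.matrix(features)
  ld <- gauss_logdens(X, model$means, model$vars)
  e <- hmm_forward_backward(ld, model$initial, model$transition)
  list(gamma = e$gamma, loglik = e$loglik)
}

#' Balance a session's trial count by adjacent upsampling
#'
#' When a session has fewer than `target` trials, additional trial indices
#' are drawn with replacement and each duplicate is inserted adjacent to its
#' source trial, so the chronological single-switch state structure is
#' preserved. Sessions already at `target` pass through unchanged;
#' downsampling is refused.
#'
#' @param n_trials trial count of the session.
#' @param target balanced trial count (default 31).
#' @return Integer index vector of length `target` into the original trials
#'   (non-decreasing).
#' @export
balance_trials <- function(n_trials, target = 31) {
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 2)
  if (target < n_trials) stop("target below session trial count: downsampling not supported")
  if (target == n_trials) return(seq_len(n_trials))
  extra <- sample.int(n_trials, target - n_trials, replace = TRUE)
  rep(seq_len(n_trials), times = 1L + tabulate(extra, n_trials))
}

# first index of the terminal run of `value` in x, or NA if x doesn't end with it
terminal_run_start <- function(x, value) {
  n <- length(x)
  if (x[n] != value) return(NA_integer_)
  i <- n
  while (i > 1 && x[i - 1] == value) i <- i - 1
  i
}

#' Bootstrap HMM decoding of behavioral states
#'
#' The full decoding protocol: per iteration, subsample a fraction of
#' neurons, balance trials by adjacent upsampling, build PCA trial features,
#' initialize with K-means, fit the two-state HMM by Baum-Welch on a random
#' training subset of trials (chronological order preserved), Viterbi-decode
#' the full sequence, map hidden states to early/late by majority overlap
#' with behavioral labels on the training trials, and score (a) state
#' prediction accuracy on held-out trials and on all trials, and (b) the
#' switch-point error `delta_switch` = first trial of the terminal
#' predicted-late run minus the behavioral switch point. Iterations without
#' a terminal predicted-late run (or with degenerate clustering) are marked
#' invalid and excluded from summaries.
#'
#' Baum-Welch runs from two initializations per iteration — the K-means
#' assignment and a contiguous changepoint split ([changepoint_init()]) —
#' and the higher-likelihood fit is kept, the usual guard against EM local
#' optima (here: latching onto the outcome axis instead of the temporally
#' contiguous state axis).
#'
#' @param session a `ca_session`.
#' @param n_iterations bootstrap iterations (default 1000; 200 is the desk
#'   default used by [run_pipeline()]).
#' @param neuron_fraction fraction of neurons per iteration (default 0.4).
#' @param train_fraction fraction of (balanced) trials used for fitting
#'   (default 0.9).
#' @param balance_target balanced trial count (default 31).
#' @param n_components PCA components for the features (default 3).
#' @param seed optional seed.
#' @return List of class `"hmm_decode"`: `per_iteration` data.frame
#'   (valid, accuracy_all, accuracy_heldout, delta_switch) and `summary`
#'   (means, medians, SEMs over valid iterations, failure_rate).
#' @export
decode_bootstrap <- function(session, n_iterations = 1000, neuron_fraction = 0.4,
                             train_fraction = 0.9, balance_target = 31,
                             n_components = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labeling <- label_states(session$trials)
  M <- prechoice_means(session)
  N <- ncol(M)
  if (N < 5) stop("need at least 5 neurons")
  n_trials <- nrow(M)
  s_beh <- ifelse(labeling$state == "late", 2L, 1L)
  n_sub <- max(n_components, floor(neuron_fraction * N))
  res <- data.frame(iteration = seq_len(n_iterations), valid = FALSE,
                    accuracy_all = NA_real_, accuracy_heldout = NA_real_,
                    delta_switch = NA_real_)
  for (b in seq_len(n_iterations)) {
    idx_n <- sample.int(N, n_sub)
    bal <- balance_trials(n_trials, balance_target)
    s_bal <- s_beh[bal]
    sp_bal <- terminal_run_start(s_bal, 2L)
    out <- tryCatch({
      X <- pca_scores(M[bal, idx_n, drop = FALSE], n_components)
      n_bal <- nrow(X)
      train <- sort(sample.int(n_bal, round(train_fraction * n_bal)))
      heldout <- setdiff(seq_len(n_bal), train)
      Xtr <- X[train, , drop = FALSE]
      # EM from two initializations (best-WCSS K-means and contiguous
      # changepoint split); keep the higher-likelihood fit
      fits <- lapply(list(kmeans_init(Xtr, k = 2), changepoint_init(Xtr)),
                     function(ini) fit_baum_welch(Xtr, ini))
      lls <- vapply(fits, function(m) max(m$log_likelihood_trace), numeric(1))
      model <- fits[[which.max(lls)]]
      path <- viterbi(model, X)
      # hidden-state -> behavior-label mapping by majority overlap on training trials
      map <- vapply(1:2, function(h) {
        hit <- path[train] == h
        if (!any(hit)) return(1L)
        if (mean(s_bal[train][hit] == 2L) > 0.5) 2L else 1L
      }, integer(1))
      pred <- map[path]
      acc_all <- mean(pred == s_bal)
      acc_held <- if (length(heldout)) mean(pred[heldout] == s_bal[heldout]) else NA_real_
      pred_sp <- terminal_run_start(pred, 2L)
      list(valid = !is.na(pred_sp), accuracy_all = acc_all,
           accuracy_heldout = acc_held,
           delta_switch = if (!is.na(pred_sp)) pred_sp - sp_bal else NA_real_)
    }, error = function(e) list(valid = FALSE, accuracy_all = NA_real_,
                                accuracy_heldout = NA_real_, delta_switch = NA_real_))
    res$valid[b] <- out$valid
    res$accuracy_all[b] <- out$accuracy_all
    res$accuracy_heldout[b] <- out$accuracy_heldout
    res$delta_switch[b] <- out$delta_switch
  }
  ok <- res[res$valid, , drop = FALSE]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- list(
    n_valid = nrow(ok), failure_rate = 1 - nrow(ok) / n_iterations,
    accuracy_all_mean = mean(ok$accuracy_all),
    accuracy_all_median = stats::median(ok$accuracy_all),
    accuracy_all_sem = sem(ok$accuracy_all),
    accuracy_heldout_mean = mean(ok$accuracy_heldout, na.rm = TRUE),
    accuracy_heldout_median = stats::median(ok$accuracy_heldout, na.rm = TRUE),
    accuracy_heldout_sem = sem(ok$accuracy_heldout[!is.na(ok$accuracy_heldout)]),
    delta_switch_mean = mean(ok$delta_switch),
    delta_switch_median = stats::median(ok$delta_switch),
    delta_switch_sem = sem(ok$delta_switch)
  )
  structure(list(per_iteration = res, summary = summary), class = "hmm_decode")
}
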