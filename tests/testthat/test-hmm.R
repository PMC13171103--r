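# brute-force HMM oracles for small T
brute_viterbi <- function(logdens, logpi, logA) {
  T_len <- nrow(logdens); K <- ncol(logdens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  lp <- apply(paths, 1, function(p) {
    v <- logpi[p[1]] + logdens[1, p[1]]
    for (t in 2:T_len) v <- v + logA[p[t - 1], p[t]] + logdens[t, p[t]]
    v
  })
  paths[which.max(lp), ]
}

brute_loglik <- function(logdens, logpi, logA) {
  T_len <- nrow(logdens); K <- ncol(logdens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  lp <- apply(paths, 1, function(p) {
    v <- logpi[p[1]] + logdens[1, p[1]]
    for (t in 2:T_len) v <- v + logA[p[t - 1], p[t]] + logdens[t, p[t]]
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

random_model <- function(T_len, d = 2) {
  A <- matrix(runif(4, 0.05, 1), 2); A <- A / rowSums(A)
  pi0 <- runif(2, 0.1, 1); pi0 <- pi0 / sum(pi0)
  means <- matrix(rnorm(2 * d, 0, 2), 2)
  vars <- matrix(runif(2 * d, 0.3, 2), 2)
  X <- matrix(rnorm(T_len * d), T_len)
  list(model = list(initial = pi0, transition = A, means = means, vars = vars),
       X = X)
}

test_that("viterbi agrees with exhaustive path enumeration", {
  set.seed(10)
  for (i in 1:10) {
    T_len <- sample(2:9, 1)
    rm_ <- random_model(T_len)
    path <- viterbi(rm_$model, rm_$X)
    ld <- setshift:::gauss_logdens(rm_$X, rm_$model$means, rm_$model$vars)
    brute <- brute_viterbi(ld, log(rm_$model$initial), log(rm_$model$transition))
    expect_equal(as.integer(path), as.integer(brute))
  }
})

test_that("viterbi ties break toward the lower state index", {
  model <- list(initial = c(0.5, 0.5), transition = matrix(0.5, 2, 2),
                means = matrix(0, 2, 1), vars = matrix(1, 2, 1))
  path <- viterbi(model, matrix(rnorm(6), 6))
  expect_true(all(path == 1L))
})

test_that("viterbi equals nearest-mean labels for well-separated emissions", {
  set.seed(11)
  model <- list(initial = c(0.5, 0.5), transition = matrix(0.5, 2, 2),
                means = matrix(c(-10, 10), 2, 1), vars = matrix(1, 2, 1))
  X <- matrix(c(rnorm(5, -10), rnorm(5, 10)), ncol = 1)
  expect_equal(as.integer(viterbi(model, X)), rep(c(1L, 2L), each = 5))
})

test_that("forward-backward posteriors normalize and match the brute-force likelihood", {
  set.seed(12)
  for (i in 1:10) {
    rm_ <- random_model(sample(2:8, 1))
    post <- posterior_states(rm_$model, rm_$X)
    expect_equal(rowSums(post$gamma), rep(1, nrow(rm_$X)), tolerance = 1e-9)
    ld <- setshift:::gauss_logdens(rm_$X, rm_$model$means, rm_$model$vars)
    expect_equal(post$loglik,
                 brute_loglik(ld, log(rm_$model$initial), log(rm_$model$transition)),
                 tolerance = 1e-8)
  }
})

test_that("kmeans_init separates planted clusters and handles degenerate input", {
  set.seed(13)
  X <- rbind(matrix(rnorm(20 * 2, -5), ncol = 2), matrix(rnorm(20 * 2, 5), ncol = 2))
  init <- kmeans_init(X, k = 2)
  truth <- rep(1:2, each = 20)
  agree <- max(mean(init$assignment == truth), mean(init$assignment == 3 - truth))
  expect_equal(agree, 1)
  expect_equal(rowSums(init$transition), c(1, 1), tolerance = 1e-12)

  # k = 1: single cluster, trivial transition matrix
  i1 <- kmeans_init(X, k = 1)
  expect_true(all(i1$assignment == 1L))
  expect_equal(i1$transition, matrix(1, 1, 1))

  # duplicated identical points: zero within-cluster variance, floored
  Xd <- rbind(matrix(1, 10, 2), matrix(9, 10, 2))
  id <- kmeans_init(Xd, k = 2)
  expect_true(all(id$vars >= 1e-6))
})

test_that("changepoint_init finds a planted chronological split", {
  set.seed(14)
  X <- rbind(matrix(rnorm(12 * 2, 0, 0.5), ncol = 2),
             matrix(rnorm(8 * 2, 4, 0.5), ncol = 2))
  init <- changepoint_init(X)
  expect_equal(init$assignment, rep(c(1L, 2L), c(12, 8)))
})

test_that("Baum-Welch increases likelihood and recovers planted parameters", {
  set.seed(15)
  # monotone log-likelihood on random data
  for (i in 1:20) {
    X <- matrix(rnorm(40 * 2), 40)
    fit <- fit_baum_welch(X, kmeans_init(X, k = 2), max_iter = 30)
    expect_true(all(diff(fit$log_likelihood_trace) > -1e-6))
  }
  # parameter recovery: means +/-2, var 1, self-transition 0.9, T = 500
  sim_hmm <- function(T_len) {
    s <- integer(T_len); s[1] <- 1
    for (t in 2:T_len) s[t] <- if (runif(1) < 0.9) s[t - 1] else 3 - s[t - 1]
    X <- matrix(rnorm(T_len, c(-2, 2)[s], 1), ncol = 1)
    list(s = s, X = X)
  }
  sim <- sim_hmm(500)
  fit <- fit_baum_welch(sim$X, kmeans_init(sim$X, k = 2))
  expect_lt(abs(mean(diag(fit$transition)) - 0.9), 0.05)
  expect_lt(max(abs(sort(fit$means) - c(-2, 2))), 0.2)
})

test_that("single-state EM converges immediately to the sample moments", {
  set.seed(16)
  X <- matrix(rnorm(50 * 2, 3, 2), 50)
  fit <- fit_baum_welch(X, kmeans_init(X, k = 1), max_iter = 10)
  expect_true(fit$converged)
  expect_lte(length(fit$log_likelihood_trace), 2)
  expect_equal(as.numeric(fit$means), colMeans(X), tolerance = 1e-9)
  expect_equal(as.numeric(fit$vars),
               apply(X, 2, function(c) mean((c - mean(c))^2)), tolerance = 1e-9)
})

test_that("balance_trials upsamples adjacently and preserves the single switch", {
  expect_equal(balance_trials(31, 31), 1:31)
  expect_error(balance_trials(20, 10), "downsampling")
  set.seed(17)
  states <- rep(c(1L, 2L), c(12, 8))  # single early->late transition
  for (i in 1:200) {
    idx <- balance_trials(20, 31)
    expect_length(idx, 31)
    expect_true(all(diff(idx) >= 0))          # chronological
    expect_true(all(tabulate(idx, 20) >= 1))  # every trial retained
    s_bal <- states[idx]
    expect_equal(sum(diff(s_bal) != 0), 1)    # still exactly one transition
  }
})

test_that("hidden-state relabeling leaves mapped accuracy unchanged", {
  set.seed(18)
  s <- generate_session(fixed_switch_config(index = 8, n_neurons = 20, seed = 6))
  X <- trial_features(s, n_components = 3)
  fit <- fit_baum_welch(X, changepoint_init(X))
  swapped <- fit
  swapped$initial <- rev(fit$initial)
  swapped$transition <- fit$transition[2:1, 2:1]
  swapped$means <- fit$means[2:1, , drop = FALSE]
  swapped$vars <- fit$vars[2:1, , drop = FALSE]
  p1 <- viterbi(fit, X); p2 <- viterbi(swapped, X)
  expect_equal(as.integer(p1), as.integer(3L - p2))
  beh <- ifelse(label_states(s$trials)$state == "late", 2L, 1L)
  map_acc <- function(path) {
    map <- vapply(1:2, function(h) {
      hit <- path == h
      if (!any(hit)) return(1L)
      if (mean(beh[hit] == 2L) > 0.5) 2L else 1L
    }, integer(1))
    mean(map[path] == beh)
  }
  expect_equal(map_acc(p1), map_acc(p2))
})

test_that("decode_bootstrap recovers a planted strong switch signal", {
  cfg <- generator_config("control", n_neurons = 40, effect_size = 3, noise_sd = 0.5,
                          drive_noise_sd = c(choice = 0.3, history = 0.3, switch = 0.3),
                          neural_lead = 0, seed = 19)
  s <- generate_session(cfg)
  d <- decode_bootstrap(s, n_iterations = 50, seed = 20)
  expect_gte(d$summary$accuracy_all_median, 0.95)
  expect_lte(d$summary$failure_rate, 0.2)
  # deterministic under a fixed seed
  d2 <- decode_bootstrap(s, n_iterations = 50, seed = 20)
  expect_identical(d$per_iteration, d2$per_iteration)
})

test_that("pure-noise features decode near the majority-class rate", {
  cfg <- generator_config("control", n_neurons = 40, seed = 21,
                          tuning_fractions = c(choice = 0, history = 0, switch = 0))
  s <- generate_session(cfg)
  d <- decode_bootstrap(s, n_iterations = 60, seed = 22)
  lab <- label_states(s$trials)
  maj <- max(table(lab$state)) / lab$n_trials
  ok <- d$per_iteration[d$per_iteration$valid, ]
  expect_lt(abs(mean(ok$accuracy_all) - maj), 0.15)
})
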