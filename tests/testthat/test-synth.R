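test_that("generator_config validates its invariants", {
  expect_error(generator_config("control", p_correct_early = 1), "indistinguishable")
  expect_error(generator_config("control", inter_choice_interval = 10), "12 s")
  expect_error(generator_config("control", kernel = list(rise_tau = 0.5, decay_tau = 0.3)),
               "exceed")
  expect_error(generator_config("control", tuning_fractions = c(choice = 1.2, history = 0, switch = 0)),
               "\\[0, 1\\]")
  # group defaults respect the planted group-effect directions
  cc <- generator_config("control"); ct <- generator_config("test")
  expect_true(all(ct$tuning_fractions >= cc$tuning_fractions))
  expect_lt(ct$separation_scale, cc$separation_scale)
})

test_that("outcome sequences honor the criterion structure", {
  cfg <- fixed_switch_config(index = 5)
  set.seed(1)
  tr <- generate_outcome_sequence(cfg)
  # all trials from the switch on are correct, the one before is the last error
  expect_true(all(tr$outcome[5:nrow(tr)] == "correct"))
  expect_identical(tr$outcome[4], "incorrect")
  expect_gte(sum(cumprod(rev(tr$outcome == "correct"))), 6)
  expect_gte(sum(tr$correct_rejection), 2)
  expect_equal(label_states(tr)$switch_point, 5L)

  # determinism: same seed, same table
  set.seed(42); a <- generate_outcome_sequence(cfg)
  set.seed(42); b <- generate_outcome_sequence(cfg)
  expect_identical(a, b)
})

test_that("choice windows never overlap across generated sessions", {
  for (seed in 1:20) {
    set.seed(seed)
    tr <- generate_outcome_sequence(generator_config("test", seed = seed))
    expect_true(all(diff(tr$choice_time) >= 10))
  }
})

test_that("early-phase accuracy matches the conditional binomial oracle", {
  # fixed switch at 6: free early trials are 1..4 (trial 5 is the forced
  # error); the generator rejects sequences with < 2 incorrect trials, i.e.
  # it conditions on at least one error among the 4 free Bernoulli(0.5)
  # draws. Oracle: E[mean | Bin(4, .5) < 4] = (2 - 4/16) / (4 * 15/16) / ...
  # computed exactly below.
  cfg <- fixed_switch_config(index = 6)
  p <- 0.5; n_free <- 4
  p_all <- p^n_free
  oracle <- (n_free * p - n_free * p_all) / (n_free * (1 - p_all))
  set.seed(99)
  draws <- replicate(10000, {
    tr <- generate_outcome_sequence(cfg)
    mean(tr$outcome[1:4] == "correct")
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - oracle), 3 * se)
})

test_that("noiseless switch-tuned neuron separates late from early on every trial", {
  cfg <- generator_config("control", n_neurons = 1, noise_sd = 0,
                          drive_noise_sd = c(choice = 0, history = 0, switch = 0),
                          neural_lead = 0,
                          tuning_fractions = c(choice = 0, history = 0, switch = 1),
                          switch_trial = list(type = "fixed", index = 8), seed = 2)
  s <- generate_session(cfg)
  tens <- extract_window(session_fluor(s), s$trials, c(-5, 0))
  m <- apply(tens, 1, mean)
  lab <- label_states(s$trials)
  expect_gt(min(m[lab$state == "late"]), max(m[lab$state == "early"]))
})

test_that("calcium kernel peaks after onset and decays fast", {
  t <- seq(0, 4, by = 0.05)
  k <- calcium_kernel(t, rise_tau = 0.1, decay_tau = 0.5, normalize = "peak")
  expect_equal(max(k), 1, tolerance = 1e-3)  # sampled grid vs analytic peak
  peak_t <- t[which.max(k)]
  expect_gt(peak_t, 0)
  expect_lt(max(k[t >= peak_t + 2]), 0.05)
  expect_equal(calcium_kernel(-1, normalize = "peak"), 0)
  expect_equal(sum(calcium_kernel(t, normalize = "sum")), 1, tolerance = 1e-12)
})

test_that("untuned neurons are exchangeable between states", {
  # permutation p-values for untuned neurons should be uniform: check the
  # rejection rate at alpha = 0.05 against its binomial band
  cfg <- generator_config("control", n_neurons = 150, seed = 3,
                          tuning_fractions = c(choice = 0, history = 0, switch = 0))
  s <- generate_session(cfg)
  res <- classify_session(s, n_perm = 200, seed = 4)
  fpr <- mean(res$responsive_switch)
  expect_lt(abs(fpr - 0.05), 1.96 * sqrt(0.05 * 0.95 / 150) + 0.01)
})

test_that("cohorts are balanced, deterministic and carry exact planted counts", {
  cc <- generator_config("control", n_neurons = 40)
  ct <- generator_config("test", n_neurons = 40)
  cohort <- generate_cohort(cc, ct, n_per_group = 4, seed = 11)
  groups <- vapply(cohort, function(s) s$meta$group, character(1))
  expect_equal(sum(groups == "control"), 4)
  expect_equal(sum(groups == "test"), 4)
  # fixed-count planting: every session carries round(f * N) tuned neurons
  for (s in cohort) {
    f <- if (s$meta$group == "control") cc$tuning_fractions else ct$tuning_fractions
    for (v in names(f)) {
      expect_equal(sum(grepl(v, s$truth$tuned_variables)), round(f[[v]] * 40))
    }
  }
  cohort2 <- generate_cohort(cc, ct, n_per_group = 4, seed = 11)
  expect_equal(cohort[[3]]$traces, cohort2[[3]]$traces)
  expect_identical(cohort[[5]]$trials, cohort2[[5]]$trials)
})

test_that("trace generation refuses runaway sessions", {
  cfg <- generator_config("control", max_samples = 100, seed = 1)
  set.seed(1)
  tr <- generate_outcome_sequence(cfg)
  expect_error(generate_traces(cfg, tr), "max_samples")
})
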