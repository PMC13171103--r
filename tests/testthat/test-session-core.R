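test_that("zscore_per_neuron gives zero-mean unit-sd rows and is idempotent in value", {
  set.seed(1)
  F <- fm(matrix(rnorm(5 * 100, 3, 2), 5))
  Z <- zscore_per_neuron(F)
  expect_equal(unname(rowMeans(Z$values)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(Z$values, 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_identical(Z$units, "zscored")
  # applying the transform again (as raw input) changes nothing
  Z2 <- zscore_per_neuron(fm(Z$values))
  expect_equal(Z2$values, Z$values, tolerance = 1e-12)
  expect_error(zscore_per_neuron(Z), "already z-scored")
})

test_that("zscore_per_neuron names the degenerate neuron", {
  F <- fm(rbind(n1 = rnorm(50), n2 = rep(2, 50)))
  expect_error(zscore_per_neuron(F), "n2")
})

test_that("bin_activity averages half-open bins and drops the trailing partial", {
  # hand example: [0,1,2,3] at 20 Hz, 100 ms bins -> [0.5, 2.5]
  F <- fm(matrix(0:3, 1))
  b <- bin_activity(F, 0.1)
  expect_equal(as.numeric(b$values), c(0.5, 2.5))

  # 50 ms bins at 20 Hz: identity
  b2 <- bin_activity(F, 0.05)
  expect_equal(as.numeric(b2$values), 0:3)

  # constant trace stays constant; trailing partial dropped
  F3 <- fm(matrix(7, 1, 5))
  b3 <- bin_activity(F3, 0.1)
  expect_equal(as.numeric(b3$values), c(7, 7))

  expect_error(bin_activity(F, 0.01), "sample spacing")
})

test_that("extract_window yields the right bin counts and aligned content", {
  cfg <- fixed_switch_config()
  s <- generate_session(cfg)
  F <- zscore_per_neuron(session_fluor(s))
  pre <- extract_window(F, s$trials, c(-5, 0))
  expect_equal(dim(pre), c(nrow(s$trials), cfg$n_neurons, 100))
  full <- extract_window(F, s$trials, c(-5, 5))
  expect_equal(dim(full)[3], 200)

  # impulse placed at a known choice time appears only in post-onset bins
  tr <- make_trials("CCCCCC")
  n_samp <- 20 * 120
  x <- matrix(0, 1, n_samp)
  times <- (seq_len(n_samp) - 1) / 20
  x[1, which(times >= tr$choice_time[2])[1] + 0:3] <- 5
  tens <- extract_window(fm(x), tr, c(-5, 5))
  pre_bins <- attr(tens, "bin_centers") < 0
  expect_true(all(tens[2, 1, pre_bins] == 0))
  expect_gt(sum(tens[2, 1, !pre_bins]), 0)

  # out-of-range trials are reported by id
  bad <- make_trials("CCCCCC", start = 2)
  expect_error(extract_window(fm(x), bad, c(-5, 0)), "trial_id: 1")
})

test_that("window-then-mean equals the direct mean over the same samples", {
  set.seed(3)
  n_samp <- 20 * 200
  F <- fm(matrix(rnorm(3 * n_samp), 3))
  trials <- make_trials("ICCCCCC")
  tens <- extract_window(F, trials, c(-5, 0))
  M <- trial_mean_prechoice(tens)
  for (i in seq_len(nrow(trials))) {
    rel <- F$sample_times - trials$choice_time[i]
    idx <- rel >= -5 - 1e-9 & rel < -1e-9
    expect_equal(M[i, ], rowMeans(F$values[, idx]), tolerance = 1e-12)
  }
})

test_that("detect_transients handles boxcars, hysteresis and offsets", {
  z <- matrix(0, 1, 20 * 60)
  det0 <- detect_transients(fm(z, units = "zscored"))
  expect_equal(det0$summary$n_events, 0L)

  # one 1 s boxcar at z = 3
  z[1, 101:120] <- 3
  det <- detect_transients(fm(z, units = "zscored"))
  expect_equal(det$summary$n_events, 1L)
  expect_equal(det$events$peak_amplitude_z, 3)
  expect_equal(det$events$duration_s, 1.0, tolerance = 0.06)

  # count invariant to a constant offset applied before z-scoring
  set.seed(9)
  raw <- matrix(rnorm(2000), 1)
  raw[1, 300:310] <- raw[1, 300:310] + 8
  n1 <- detect_transients(zscore_per_neuron(fm(raw)))$summary$n_events
  n2 <- detect_transients(zscore_per_neuron(fm(raw + 5)))$summary$n_events
  expect_equal(n1, n2)

  expect_error(detect_transients(fm(z, units = "zscored"), theta_on = 1, theta_off = 2),
               "theta_off")
  expect_error(detect_transients(fm(raw)), "z-scored")
})

test_that("planted kernel events are recovered at default thresholds", {
  set.seed(11)
  dt <- 0.05
  n_samp <- 20 * 600
  onsets <- sort(sample(seq(100, n_samp - 100, by = 120), 60))
  x <- rnorm(n_samp, 0, 0.3)
  kern <- calcium_kernel(seq(0, 4, by = dt), normalize = "peak")
  for (o in onsets) {
    idx <- o + seq_along(kern) - 1
    idx <- idx[idx <= n_samp]
    x[idx] <- x[idx] + 3.5 * kern[seq_along(idx)]
  }
  det <- detect_transients(fm(matrix(x, 1), units = "zscored"))
  # recall: detected onset within 0.5 s of a planted onset
  hits <- sum(vapply(onsets, function(o) {
    any(abs(det$events$onset_s - (o - 1) * dt) < 0.5)
  }, logical(1)))
  expect_gte(hits / length(onsets), 0.95)
})

test_that("sessions round-trip through the directory layout", {
  s <- generate_session(tiny_config())
  dir <- tempfile("sess")
  write_session(s, dir)
  expect_true(all(file.exists(file.path(dir, c("traces.csv", "trials.csv",
                                               "meta.json", "truth.csv")))))
  s2 <- read_session(dir)
  expect_equal(unname(s2$traces), unname(s$traces), tolerance = 1e-9)
  expect_equal(s2$sample_times, s$sample_times, tolerance = 1e-9)
  expect_equal(s2$trials$outcome, s$trials$outcome)
  expect_equal(s2$trials$choice_time, s$trials$choice_time, tolerance = 1e-9)
  expect_equal(s2$truth$tuned_variables, s$truth$tuned_variables)
  expect_identical(s2$meta$group, "control")
  unlink(dir, recursive = TRUE)
})
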