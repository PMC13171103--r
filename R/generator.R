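#' Configuration for the synthetic session generator
#'
#' Builds a validated configuration describing one simulated set-shifting
#' session: the behavioral trial process (early trial-and-error phase followed
#' by a terminal run of consecutive correct trials), the neurons' planted
#' tuning, and the calcium-trace model. Group defaults encode the study
#' conditions this generator emulates: the `test` group (locus coeruleus
#' inhibition) has larger tuned fractions per variable, and a smaller
#' `separation_scale`, i.e. a reduced early/late population mean shift.
#'
#' Tuned fractions default to (choice, history, switch) = (0.10, 0.06, 0.17)
#' for controls and (0.17, 0.13, 0.25) for the test group, the responsive
#' fractions observed in the real cohorts these simulations stand in for.
#'
#' @param group `"control"` or `"test"`; selects group-level defaults.
#' @param n_neurons number of simulated neurons.
#' @param frame_rate imaging rate in Hz.
#' @param n_trials_nominal expected total trial count; the latent switch index
#'   is geometric with success probability `1/(n_trials_nominal - 6)` unless
#'   `switch_trial` fixes it.
#' @param n_trials_max sessions longer than this are resampled (the decoding
#'   protocol balances all sessions to this count).
#' @param inter_choice_interval mean spacing between choices in seconds
#'   (must be >= 12 so +/-5 s choice windows never overlap).
#' @param p_correct_early probability that an early-phase trial is correct;
#'   must be < 1 or the early and late states would be indistinguishable.
#' @param p_correct_rejection probability that a correct trial carries a
#'   correct-rejection flag.
#' @param switch_trial either `list(type = "geometric", p = ...)` or
#'   `list(type = "fixed", index = k)`; `NULL` derives the geometric default.
#' @param tuning_fractions named numeric vector with entries `choice`,
#'   `history`, `switch`: probability that a neuron is tuned to each variable.
#' @param mixed_tuning_rate latent correlation (Gaussian copula) between the
#'   three per-variable tuning indicators; raises co-tuning (mixed
#'   selectivity) without changing the marginal fractions.
#' @param effect_size amplitude, in z-units, of the sustained pre-choice drive
#'   a tuned neuron receives on its preferred trials.
#' @param separation_scale multiplier on the extra early/late population mean
#'   shift (2 z at scale 1) carried by switch-tuned neurons.
#' @param drive_noise_sd named numeric vector (`choice`, `history`, `switch`):
#'   standard deviation of a zero-mean per-trial fluctuation of each
#'   variable's drive amplitude, shared by all neurons tuned to that variable
#'   on every trial. This models trial-to-trial population covariability and
#'   sets the ceiling of population decoding accuracy; per-neuron window
#'   means stay far enough above it for single-neuron tuning recovery.
#'   Defaults are group-dependent (test noisier: (1.5, 1.5, 1.5) vs control
#'   (0.5, 0.4, 1.5) z), the planted counterpart of noisier task engagement
#'   under locus coeruleus inhibition.
#' @param neural_lead number of trials before the behavioral switch on which
#'   the switch-population drive is already on at half amplitude: rule
#'   acquisition precedes the behavioral criterion run. Group-dependent
#'   default (control 1, test 3), emulating the larger anticipatory offset of
#'   the neural switch under locus coeruleus inhibition.
#' @param min_switch_index smallest admissible latent switch trial (default
#'   7, so every session has enough distinct early trials for all contrasts
#'   and for trial-balanced decoding).
#' @param kernel list with `rise_tau` and `decay_tau` (seconds) of the
#'   difference-of-exponentials calcium kernel.
#' @param noise_sd standard deviation of the i.i.d. Gaussian baseline noise.
#' @param max_samples guard on the implied trace length.
#' @param seed integer seed; every draw in the session derives from it.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(group = c("control", "test"),
                             n_neurons = 60,
                             frame_rate = 20,
                             n_trials_nominal = NULL,
                             n_trials_max = 31,
                             inter_choice_interval = 13,
                             p_correct_early = 0.5,
                             p_correct_rejection = 0.5,
                             switch_trial = NULL,
                             tuning_fractions = NULL,
                             mixed_tuning_rate = 0.3,
                             effect_size = 2,
                             separation_scale = NULL,
                             drive_noise_sd = NULL,
                             neural_lead = NULL,
                             min_switch_index = 7,
                             kernel = list(rise_tau = 0.1, decay_tau = 0.5),
                             noise_sd = 1,
                             max_samples = 500000L,
                             seed = 1L) {
  group <- match.arg(group)
  if (is.null(tuning_fractions)) {
    tuning_fractions <- if (group == "control") {
      c(choice = 0.10, history = 0.06, switch = 0.17)
    } else {
      c(choice = 0.17, history = 0.13, switch = 0.25)
    }
  }
  if (is.null(separation_scale)) {
    separation_scale <- if (group == "control") 1.0 else 0.3
  }
  if (is.null(drive_noise_sd)) {
    # trial-to-trial population covariability; larger in the test group
    # (noisier engagement under locus coeruleus inhibition)
    drive_noise_sd <- if (group == "control") {
      c(choice = 0.5, history = 0.4, switch = 1.5)
    } else {
      c(choice = 1.5, history = 1.5, switch = 1.5)
    }
  }
  if (is.null(neural_lead)) {
    neural_lead <- if (group == "control") 1 else 3
  }
  if (is.null(n_trials_nominal)) {
    n_trials_nominal <- if (group == "control") 15 else 24
  }
  if (is.null(switch_trial)) {
    # switch index = min_switch_index + geometric; p set so the expected
    # session length (~ switch + 5.5 criterion-run trials) matches nominal
    mean_extra <- max(1, n_trials_nominal - 5.5 - min_switch_index)
    switch_trial <- list(type = "geometric", p = 1 / (1 + mean_extra))
  }
  cfg <- list(
    group = group, n_neurons = as.integer(n_neurons),
    frame_rate = frame_rate, n_trials_nominal = n_trials_nominal,
    n_trials_max = as.integer(n_trials_max),
    inter_choice_interval = inter_choice_interval,
    p_correct_early = p_correct_early,
    p_correct_rejection = p_correct_rejection,
    switch_trial = switch_trial,
    tuning_fractions = tuning_fractions,
    mixed_tuning_rate = mixed_tuning_rate,
    effect_size = effect_size, separation_scale = separation_scale,
    drive_noise_sd = drive_noise_sd, neural_lead = as.integer(neural_lead),
    min_switch_index = as.integer(min_switch_index),
    kernel = kernel, noise_sd = noise_sd,
    max_samples = as.integer(max_samples), seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  probs <- c(cfg$p_correct_early, cfg$p_correct_rejection,
             cfg$tuning_fractions, cfg$mixed_tuning_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$p_correct_early >= 1) {
    stop("p_correct_early must be < 1: early and late states would be indistinguishable")
  }
  if (!all(c("choice", "history", "switch") %in% names(cfg$tuning_fractions))) {
    stop("tuning_fractions needs entries named choice, history, switch")
  }
  if (cfg$inter_choice_interval < 12) {
    stop("inter_choice_interval must be >= 12 s so +/-5 s choice windows never overlap")
  }
  if (cfg$kernel$rise_tau <= 0 || cfg$kernel$decay_tau <= 0) {
    stop("kernel time constants must be positive")
  }
  if (cfg$kernel$decay_tau <= cfg$kernel$rise_tau) {
    stop("kernel decay_tau must exceed rise_tau")
  }
  if (cfg$n_neurons < 1 || cfg$frame_rate <= 0 || cfg$noise_sd < 0) {
    stop("invalid n_neurons, frame_rate or noise_sd")
  }
  if (!all(c("choice", "history", "switch") %in% names(cfg$drive_noise_sd)) ||
      any(cfg$drive_noise_sd < 0)) {
    stop("drive_noise_sd needs non-negative entries named choice, history, switch")
  }
  if (cfg$neural_lead < 0) stop("neural_lead must be >= 0")
  st <- cfg$switch_trial
  ok <- is.list(st) && ((identical(st$type, "geometric") && st$p > 0 && st$p < 1) ||
                          (identical(st$type, "fixed") && st$index >= 1))
  if (!ok) stop("switch_trial must be list(type='geometric', p=..) or list(type='fixed', index=..)")
  invisible(cfg)
}

#' Simulate the outcome sequence of one set-shifting session
#'
#' Draws a latent switch trial, emits Bernoulli(`p_correct_early`) outcomes
#' before it and all-correct outcomes from it on, and extends the sequence
#' until the stage criterion is satisfiable (terminal run of at least six
#' consecutive correct trials, at least two correct rejections). The trial
#' immediately preceding the switch is always an error, so the behavioral
#' switch point (start of the last consecutive-correct run) coincides with the
#' planted index. Sequences containing a premature run of six correct trials,
#' or exceeding `n_trials_max`, are resampled.
#'
#' Uses the current RNG stream; callers wanting reproducibility should
#' `set.seed()` first (as [generate_session()] does).
#'
#' @param config a [generator_config()].
#' @return A `data.frame` (trial table) with columns `trial_id`, `stage`,
#'   `choice_time`, `outcome` (`"correct"`/`"incorrect"`),
#'   `correct_rejection`, and attribute `switch_index`.
#' @export
generate_outcome_sequence <- function(config) {
  validate_generator_config(config)
  for (attempt in seq_len(1000L)) {
    s <- switch(config$switch_trial$type,
      geometric = config$min_switch_index + stats::rgeom(1L, config$switch_trial$p),
      fixed = as.integer(config$switch_trial$index)
    )
    early <- if (s > 1L) stats::rbinom(s - 1L, 1L, config$p_correct_early) else integer(0)
    if (s > 1L) early[s - 1L] <- 0L  # the last error defines the switch
    outcomes <- c(early, rep(1L, 6L))
    cr <- ifelse(outcomes == 1L, stats::rbinom(length(outcomes), 1L, config$p_correct_rejection), 0L)
    # extend with correct trials until >= 2 correct rejections
    guard <- 0L
    while (sum(cr) < 2L && length(outcomes) < config$n_trials_max && guard < 100L) {
      outcomes <- c(outcomes, 1L)
      cr <- c(cr, stats::rbinom(1L, 1L, config$p_correct_rejection))
      guard <- guard + 1L
    }
    n <- length(outcomes)
    if (n > config$n_trials_max || sum(cr) < 2L) next
    # premature criterion run in the early phase would have ended the session
    if (s > 1L && max_run(early) >= 6L) next
    # analyzable sessions need both outcome classes represented
    if (s >= 3L && sum(outcomes == 0L) < 2L) next
    # and a late state that is not a sliver of a long session (population
    # analyses need both states represented after trial balancing)
    if (s > 1L && (n - s + 1L) < ceiling(0.22 * n)) next
    gaps <- config$inter_choice_interval + stats::runif(n, -1, 1)
    choice_time <- cumsum(gaps)
    trials <- data.frame(
      trial_id = seq_len(n), stage = "EDS", choice_time = choice_time,
      outcome = ifelse(outcomes == 1L, "correct", "incorrect"),
      correct_rejection = cr == 1L, stringsAsFactors = FALSE
    )
    attr(trials, "switch_index") <- s
    return(trials)
  }
  stop("failed to draw a valid outcome sequence in 1000 attempts; check config")
}

max_run <- function(x01) {
  if (length(x01) == 0) return(0L)
  r <- rle(x01)
  w <- r$values == 1L
  if (!any(w)) 0L else max(r$lengths[w])
}

#' Difference-of-exponentials calcium kernel
#'
#' `k(t) = exp(-t/decay_tau) - exp(-t/rise_tau)` for `t >= 0`, normalized
#' either to unit peak (shape inspection) or unit sum (trace synthesis, so a
#' sustained drive of amplitude `a` plateaus at `a`). Defaults are
#' GCaMP6f-like (rise 0.1 s, decay 0.5 s).
#'
#' @param t time points in seconds (values < 0 give 0).
#' @param rise_tau,decay_tau time constants in seconds, `decay_tau > rise_tau`.
#' @param normalize `"peak"` or `"sum"`.
#' @return Numeric vector of kernel values at `t`.
#' @export
calcium_kernel <- function(t, rise_tau = 0.1, decay_tau = 0.5,
                           normalize = c("peak", "sum")) {
  normalize <- match.arg(normalize)
  stopifnot(decay_tau > rise_tau, rise_tau > 0)
  k <- ifelse(t < 0, 0, exp(-t / decay_tau) - exp(-t / rise_tau))
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  if (normalize == "peak") k / peak else k / sum(k)
}

#' Synthesize calcium traces for a trial table
#'
#' Each neuron's trace is i.i.d. Gaussian baseline noise plus, for every
#' variable the neuron is tuned to, a sustained drive over the 5 s preceding
#' each choice on which the variable takes its preferred value (upcoming
#' correct choice; previous trial correct; late rule-following state),
#' convolved with the calcium kernel. Switch-tuned neurons additionally carry
#' the early/late population mean shift, `2 * separation_scale` z-units.
#' Planted tuning (ground truth) is drawn per neuron via a Gaussian copula
#' whose correlation `mixed_tuning_rate` controls mixed selectivity while
#' preserving the marginal tuned fractions.
#'
#' Uses the current RNG stream (see [generate_session()] for the seeded
#' entry point).
#'
#' @param config a [generator_config()].
#' @param trials trial table from [generate_outcome_sequence()].
#' @return A session object: list with `traces` (neurons x samples matrix),
#'   `sample_times`, `trials`, `meta`, and `truth` (per-neuron tuned
#'   variables).
#' @export
generate_traces <- function(config, trials) {
  validate_generator_config(config)
  dt <- 1 / config$frame_rate
  t_end <- max(trials$choice_time) + 6
  sample_times <- seq(0, t_end, by = dt)
  n_samples <- length(sample_times)
  if (n_samples > config$max_samples) {
    stop("implied trace length (", n_samples, " samples) exceeds max_samples cap")
  }
  if (min(trials$choice_time) < 5 || max(trials$choice_time) > t_end - 5) {
    stop("choice times must sit >= 5 s from both session edges")
  }

  # planted tuning: exactly round(f*N) neurons per variable, selected by
  # rank-thresholding correlated Gaussian copula scores (common factor with
  # loading mixed_tuning_rate), so marginal counts are exact while co-tuning
  # (mixed selectivity) is controlled
  f <- config$tuning_fractions[c("choice", "history", "switch")]
  rho <- config$mixed_tuning_rate
  z0 <- stats::rnorm(config$n_neurons)
  tuned <- vapply(seq_along(f), function(v) {
    zv <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(config$n_neurons)
    rank(zv, ties.method = "first") <= round(f[v] * config$n_neurons)
  }, logical(config$n_neurons))
  tuned <- matrix(tuned, nrow = config$n_neurons,
                  dimnames = list(NULL, names(f)))

  # per-trial drive amplitudes: preferred-condition amplitude plus a shared
  # zero-mean fluctuation (population trial-to-trial covariability)
  labeling <- label_states(trials)
  n_trials <- nrow(trials)
  prev_correct <- c(NA, utils::head(trials$outcome, -1) == "correct")
  pref <- list(
    choice = as.numeric(trials$outcome == "correct"),
    history = ifelse(is.na(prev_correct), NA_real_, as.numeric(prev_correct)),
    switch = as.numeric(labeling$state == "late")
  )
  if (config$neural_lead > 0) {
    # rule acquisition slightly precedes the behavioral switch: half-amplitude
    # switch drive on the lead trials
    lead_trials <- (labeling$switch_point - config$neural_lead):(labeling$switch_point - 1)
    lead_trials <- lead_trials[lead_trials >= 1]
    pref$switch[lead_trials] <- 0.5
  }
  amp <- c(choice = config$effect_size, history = config$effect_size,
           switch = config$effect_size + 2 * config$separation_scale)

  kern_t <- seq(0, config$kernel$decay_tau * 8, by = dt)
  kern <- calcium_kernel(kern_t, config$kernel$rise_tau, config$kernel$decay_tau,
                         normalize = "sum")

  traces <- matrix(stats::rnorm(config$n_neurons * n_samples, 0, config$noise_sd),
                   nrow = config$n_neurons)
  for (v in names(f)) {
    eta <- stats::rnorm(n_trials, 0, config$drive_noise_sd[[v]])
    if (!any(tuned[, v])) next
    height <- amp[[v]] * pref[[v]] + eta
    height[is.na(height)] <- 0  # trial 1 carries no history drive
    drive <- numeric(n_samples)
    for (i in seq_len(n_trials)) {
      if (height[i] == 0) next
      on <- trials$choice_time[i] - 5
      idx <- which(sample_times >= on & sample_times < trials$choice_time[i])
      drive[idx] <- drive[idx] + height[i]
    }
    resp <- conv_truncated(drive, kern)
    traces[tuned[, v], ] <- sweep(traces[tuned[, v], , drop = FALSE], 2, resp, "+")
  }
  neuron_id <- sprintf("n%03d", seq_len(config$n_neurons))
  rownames(traces) <- neuron_id
  truth <- data.frame(
    neuron_id = neuron_id,
    tuned_variables = apply(tuned, 1, function(r) paste(names(f)[r], collapse = ";")),
    stringsAsFactors = FALSE
  )
  session <- list(
    traces = traces, sample_times = sample_times, trials = trials,
    meta = list(mouse_id = NA_character_, group = config$group,
                frame_rate = config$frame_rate, seed = config$seed,
                config = config[setdiff(names(config), "seed")]),
    truth = truth
  )
  class(session) <- "ca_session"
  session
}

# one-sided convolution truncated to the input length
conv_truncated <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  out
}

#' Generate one complete synthetic session
#'
#' Seeds the RNG from `config$seed`, draws the outcome sequence, then the
#' traces; identical configs yield identical sessions.
#'
#' @param config a [generator_config()].
#' @param mouse_id optional identifier stored in the metadata.
#' @return A `ca_session` object.
#' @export
generate_session <- function(config, mouse_id = "m01") {
  set.seed(config$seed)
  trials <- generate_outcome_sequence(config)
  session <- generate_traces(config, trials)
  session$meta$mouse_id <- mouse_id
  session
}

#' Generate a two-group cohort of synthetic sessions
#'
#' Per-session seeds are derived deterministically from the master seed, so a
#' cohort is fully reproducible (and byte-identical on disk) given
#' `(configs, n_per_group, seed)`.
#'
#' @param config_control,config_test [generator_config()]s for the two groups.
#' @param n_per_group sessions (mice) per group.
#' @param seed master integer seed.
#' @return List of `ca_session` objects, controls first.
#' @export
generate_cohort <- function(config_control, config_test, n_per_group = 4, seed = 1) {
  sessions <- vector("list", 2 * n_per_group)
  k <- 0L
  for (g in c("control", "test")) {
    cfg <- if (g == "control") config_control else config_test
    stopifnot(identical(cfg$group, g))
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(seed, k)
      sessions[[k]] <- generate_session(cfg_i, mouse_id = sprintf("%s%02d", substr(g, 1, 1), i))
    }
  }
  sessions
}
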