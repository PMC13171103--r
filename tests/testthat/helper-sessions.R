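# Shared fixtures: small deterministic sessions built in code.

tiny_config <- function(group = "control", seed = 7, ...) {
  generator_config(group = group, n_neurons = 30, seed = seed, ...)
}

# a session with a fixed switch index, handy when tests need known structure
fixed_switch_config <- function(index = 8, n_neurons = 20, seed = 5, ...) {
  generator_config("control", n_neurons = n_neurons, seed = seed,
                   switch_trial = list(type = "fixed", index = index), ...)
}

# minimal trial table builder: outcomes as "C"/"I" string, choices spaced 13 s
make_trials <- function(outcomes, cr = NULL, start = 13) {
  o <- strsplit(outcomes, "")[[1]]
  n <- length(o)
  if (is.null(cr)) cr <- rep(FALSE, n)
  data.frame(
    trial_id = seq_len(n), stage = "EDS",
    choice_time = start + (seq_len(n) - 1) * 13,
    outcome = ifelse(o == "C", "correct", "incorrect"),
    correct_rejection = cr, stringsAsFactors = FALSE
  )
}

# fluor_matrix from a plain matrix at 20 Hz
fm <- function(values, frame_rate = 20, units = "raw") {
  fluor_matrix(values, (seq_len(ncol(values)) - 1) / frame_rate, units)
}
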