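#' Fluorescence matrix container
#'
#' Thin container pairing a neurons-by-samples activity matrix with its
#' (uniformly spaced) sample times and a units flag, so downstream stages can
#' refuse raw where z-scored input is required.
#'
#' @param values matrix, neurons in rows, samples in columns.
#' @param sample_times numeric vector of sample times in seconds; must be
#'   strictly increasing with uniform spacing (1e-9 s tolerance).
#' @param units `"raw"` or `"zscored"`.
#' @return A list of class `"fluor_matrix"`.
#' @export
fluor_matrix <- function(values, sample_times, units = c("raw", "zscored")) {
  units <- match.arg(units)
  stopifnot(is.matrix(values), ncol(values) == length(sample_times))
  d <- diff(sample_times)
  if (length(d) && (any(d <= 0) || max(abs(d - d[1])) > 1e-9)) {
    stop("sample_times must be strictly increasing with uniform spacing")
  }
  structure(list(values = values, sample_times = sample_times, units = units),
            class = "fluor_matrix")
}

#' Extract a session's traces as a fluor_matrix
#' @param session a `ca_session`.
#' @return A raw-units `fluor_matrix`.
#' @export
session_fluor <- function(session) {
  fluor_matrix(session$traces, session$sample_times, "raw")
}

#' Z-score each neuron across the whole session
#'
#' Each row is centered and scaled to unit sample standard deviation
#' (denominator `n - 1`), the per-neuron normalization applied before every
#' analysis stage.
#'
#' @param F a raw-units [fluor_matrix()].
#' @return A z-scored `fluor_matrix`.
#' @export
zscore_per_neuron <- function(F) {
  stopifnot(inherits(F, "fluor_matrix"))
  if (F$units != "raw") stop("input already z-scored")
  m <- rowMeans(F$values)
  s <- apply(F$values, 1, stats::sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    nm <- rownames(F$values)[bad] %||% as.character(bad)
    stop("zero-variance neuron(s): ", paste(nm, collapse = ", "))
  }
  fluor_matrix((F$values - m) / s, F$sample_times, "zscored")
}

#' Average activity into non-overlapping time bins
#'
#' Bins are half-open `[t, t + bin_width)` anchored at the first sample time;
#' each bin value is the mean of the samples whose timestamps fall in it.
#' A trailing partial bin (one whose right edge exceeds the recording) is
#' dropped rather than padded.
#'
#' @param F a [fluor_matrix()].
#' @param bin_width bin width in seconds; must be >= the sample spacing.
#' @return A `fluor_matrix` at the binned resolution (sample times are bin
#'   centers).
#' @export
bin_activity <- function(F, bin_width) {
  stopifnot(inherits(F, "fluor_matrix"))
  dt <- F$sample_times[2] - F$sample_times[1]
  if (bin_width < dt - 1e-12) stop("bin_width must be >= sample spacing")
  t0 <- F$sample_times[1]
  rel <- F$sample_times - t0
  idx <- floor(rel / bin_width + 1e-9)
  span <- rel[length(rel)] + dt  # total covered time
  n_bins <- floor(span / bin_width + 1e-9)
  keep <- idx < n_bins
  idx <- idx[keep]
  vals <- F$values[, keep, drop = FALSE]
  counts <- tabulate(idx + 1L, nbins = n_bins)
  sums <- t(rowsum(t(vals), group = idx, reorder = TRUE))
  binned <- sweep(sums, 2, counts, "/")
  centers <- t0 + (seq_len(n_bins) - 0.5) * bin_width
  out <- fluor_matrix(binned, centers, F$units)
  out$units <- F$units
  out
}

#' Event-aligned window extraction
#'
#' Cuts choice-aligned windows out of a fluorescence matrix and averages
#' samples into half-open bins `[t, t + bin_width)` in choice-relative time,
#' with identical bin edges across trials.
#'
#' @param F a [fluor_matrix()].
#' @param trials trial table with `choice_time`.
#' @param window `c(start, end)` offsets in seconds relative to choice, e.g.
#'   `c(-5, 0)` for the pre-choice window.
#' @param bin_width bin width in seconds (default 0.05).
#' @return An `aligned_tensor`: array `[n_trials, n_neurons, n_bins]` with
#'   attributes `window`, `bin_width`, `bin_centers`.
#' @export
extract_window <- function(F, trials, window, bin_width = 0.05) {
  stopifnot(inherits(F, "fluor_matrix"), length(window) == 2, window[2] > window[1])
  n_bins <- round((window[2] - window[1]) / bin_width)
  t_min <- F$sample_times[1]
  t_max <- F$sample_times[length(F$sample_times)]
  lo <- trials$choice_time + window[1]
  hi <- trials$choice_time + window[2]
  bad <- which(lo < t_min - 1e-9 | hi > t_max + (F$sample_times[2] - F$sample_times[1]) + 1e-9)
  if (length(bad)) {
    stop("trial window(s) outside recording for trial_id: ",
         paste(trials$trial_id[bad], collapse = ", "))
  }
  n_trials <- nrow(trials)
  n_neurons <- nrow(F$values)
  out <- array(NA_real_, dim = c(n_trials, n_neurons, n_bins))
  for (i in seq_len(n_trials)) {
    rel <- F$sample_times - trials$choice_time[i]
    inwin <- which(rel >= window[1] - 1e-9 & rel < window[2] - 1e-9)
    bidx <- floor((rel[inwin] - window[1]) / bin_width + 1e-9)
    ok <- bidx >= 0 & bidx < n_bins
    inwin <- inwin[ok]; bidx <- bidx[ok]
    counts <- tabulate(bidx + 1L, nbins = n_bins)
    sums <- t(rowsum(t(F$values[, inwin, drop = FALSE]), group = bidx, reorder = TRUE))
    filled <- sort(unique(bidx)) + 1L
    mat <- matrix(NA_real_, n_neurons, n_bins)
    mat[, filled] <- sweep(sums, 2, counts[filled], "/")
    out[i, , ] <- mat
  }
  structure(out, window = window, bin_width = bin_width,
            bin_centers = window[1] + (seq_len(n_bins) - 0.5) * bin_width,
            class = "aligned_tensor")
}

#' Detect calcium transients by hysteresis thresholding
#'
#' On a z-scored trace, a transient opens when the signal exceeds `theta_on`
#' and closes when it falls below `theta_off`; multiple on-crossings inside
#' one supra-`theta_off` excursion merge into a single event. Amplitude is
#' the maximum z within the event and duration the time spent above half of
#' that amplitude (full width at half maximum within the event).
#'
#' @param F a z-scored [fluor_matrix()].
#' @param theta_on onset threshold in z (default 2).
#' @param theta_off offset threshold in z (default 0.5), must be < `theta_on`.
#' @return List with `events` (data.frame: neuron_id, onset_s,
#'   peak_amplitude_z, duration_s) and `summary` (per neuron: n_events,
#'   freq_per_min, mean_amp_z, mean_dur_s).
#' @export
detect_transients <- function(F, theta_on = 2.0, theta_off = 0.5) {
  stopifnot(inherits(F, "fluor_matrix"))
  if (F$units != "zscored") stop("detect_transients requires z-scored input")
  if (theta_off >= theta_on) stop("theta_off must be < theta_on")
  dt <- F$sample_times[2] - F$sample_times[1]
  minutes <- (length(F$sample_times) * dt) / 60
  ids <- rownames(F$values) %||% sprintf("n%03d", seq_len(nrow(F$values)))
  ev_list <- list()
  summ <- data.frame(neuron_id = ids, n_events = 0L, freq_per_min = 0,
                     mean_amp_z = NA_real_, mean_dur_s = NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(F$values))) {
    x <- F$values[i, ]
    r <- rle(x >= theta_off)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    onset <- amp <- dur <- numeric(0)
    for (j in which(r$values)) {
      seg <- starts[j]:ends[j]
      above <- seg[x[seg] > theta_on]
      if (!length(above)) next
      o <- above[1]
      a <- max(x[seg])
      d <- sum(x[o:ends[j]] >= a / 2) * dt
      onset <- c(onset, F$sample_times[o]); amp <- c(amp, a); dur <- c(dur, d)
    }
    if (length(onset)) {
      ev_list[[length(ev_list) + 1L]] <- data.frame(
        neuron_id = ids[i], onset_s = onset, peak_amplitude_z = amp,
        duration_s = dur, stringsAsFactors = FALSE)
      summ$n_events[i] <- length(onset)
      summ$freq_per_min[i] <- length(onset) / minutes
      summ$mean_amp_z[i] <- mean(amp)
      summ$mean_dur_s[i] <- mean(dur)
    }
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(neuron_id = character(0), onset_s = numeric(0),
               peak_amplitude_z = numeric(0), duration_s = numeric(0))
  list(events = events, summary = summ)
}
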