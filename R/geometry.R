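#' Trial-averaged state activity matrices for one session
#'
#' Z-scores the session, bins activity in choice-aligned 50 ms bins over the
#' ten seconds centered on choice, and averages across all trials of each
#' behavioral state, giving one `[n_bins x n_neurons]` matrix per state on a
#' common choice-relative grid (so neurons can be stacked across sessions).
#'
#' @param session a `ca_session`.
#' @param labeling optional [label_states()] result (computed if omitted).
#' @param window choice-relative window, default `c(-5, 5)`.
#' @param bin_width bin width in seconds, default 0.05.
#' @return List with `early`, `late` (bins x neurons matrices) and
#'   `bin_centers`.
#' @export
state_matrices <- function(session, labeling = NULL, window = c(-5, 5),
                           bin_width = 0.05) {
  labeling <- labeling %||% label_states(session$trials)
  Fz <- zscore_per_neuron(session_fluor(session))
  tens <- extract_window(Fz, session$trials, window, bin_width)
  early_tr <- which(labeling$state == "early")
  late_tr <- which(labeling$state == "late")
  if (!length(early_tr) || !length(late_tr)) {
    stop("both behavioral states need at least one trial")
  }
  avg <- function(idx) {
    # tens is trials x neurons x bins; average over trials, return bins x neurons
    t(colMeans(tens[idx, , , drop = FALSE], dims = 1))
  }
  list(early = avg(early_tr), late = avg(late_tr),
       bin_centers = attr(tens, "bin_centers"))
}

# Gaussian smoothing along time (rows) with a row-normalized banded operator,
# so edge bins are averaged over the kernel mass actually inside the window.
gaussian_smooth <- function(mat, sigma_s, bin_width) {
  if (sigma_s <= 0) return(mat)
  n <- nrow(mat)
  half <- ceiling(3 * sigma_s / bin_width)
  d <- outer(seq_len(n), seq_len(n), "-")
  W <- exp(-(d * bin_width)^2 / (2 * sigma_s^2))
  W[abs(d) > half] <- 0
  W <- W / rowSums(W)
  W %*% mat
}

#' Bootstrap early/late state trajectories over neuron subsets
#'
#' Stacks neurons across the supplied sessions (after per-session
#' trial-averaging on the common choice-relative grid), smooths each neuron's
#' trajectory with a Gaussian kernel, then repeatedly samples a random subset
#' of neurons without replacement. Both states of an iteration share the
#' identical subset and grid.
#'
#' @param sessions a `ca_session` or list of them (one group).
#' @param subset_fraction fraction of neurons per iteration (default 0.8;
#'   subset size is `floor(subset_fraction * N)`).
#' @param n_iterations bootstrap iterations (default 20).
#' @param smooth_sigma Gaussian smoothing sigma in seconds (default 0.15,
#'   truncated at 3 sigma); 0 disables smoothing.
#' @param window,bin_width passed to [state_matrices()].
#' @param seed optional seed for subset draws.
#' @return List of iterations, each `list(early, late, neurons)` with
#'   bins x subset matrices; attribute `bin_centers`.
#' @export
build_state_trajectories <- function(sessions, subset_fraction = 0.8,
                                     n_iterations = 20, smooth_sigma = 0.15,
                                     window = c(-5, 5), bin_width = 0.05,
                                     seed = NULL) {
  stopifnot(subset_fraction > 0, subset_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(sessions, "ca_session")) sessions <- list(sessions)
  mats <- lapply(sessions, state_matrices, window = window, bin_width = bin_width)
  early <- do.call(cbind, lapply(mats, `[[`, "early"))
  late <- do.call(cbind, lapply(mats, `[[`, "late"))
  early <- gaussian_smooth(early, smooth_sigma, bin_width)
  late <- gaussian_smooth(late, smooth_sigma, bin_width)
  N <- ncol(early)
  m <- max(1L, floor(subset_fraction * N))
  out <- lapply(seq_len(n_iterations), function(i) {
    idx <- if (m == N) seq_len(N) else sort(sample.int(N, m))
    list(early = early[, idx, drop = FALSE], late = late[, idx, drop = FALSE],
         neurons = idx)
  })
  attr(out, "bin_centers") <- mats[[1]]$bin_centers
  out
}

#' PCA embedding of an early/late trajectory pair
#'
#' Fits PCA jointly on the row-concatenation of both state trajectories
#' (centering each neuron), so both states live in one space, and projects
#' each onto the leading components. Six components are retained by default
#' (fewer, with a warning, when the subset has fewer neurons).
#'
#' @param pair list with `early` and `late` bins x neurons matrices sharing
#'   a neuron subset.
#' @param n_components components to retain (default 6).
#' @return List: `early`, `late` (bins x retained-PCs score matrices),
#'   `variance_explained` (per retained PC, fractions of total variance).
#' @export
pca_embed <- function(pair, n_components = 6) {
  stopifnot(ncol(pair$early) == ncol(pair$late))
  n_sub <- ncol(pair$early)
  k <- min(n_components, n_sub)
  if (k < n_components) {
    warning("subset has ", n_sub, " neurons; retaining ", k, " components")
  }
  X <- rbind(pair$early, pair$late)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  nb <- nrow(pair$early)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  list(early = scores[seq_len(nb), , drop = FALSE],
       late = scores[nb + seq_len(nb), , drop = FALSE],
       variance_explained = ve[seq_len(k)])
}

#' Euclidean distance metrics between embedded state trajectories
#'
#' Per-bin Euclidean norm of the early-late difference across retained PCs,
#' with its mean and peak over pre-choice bins (bin centers in the open
#' interval (-5, 0) s).
#'
#' @param embedded output of [pca_embed()].
#' @param bin_centers choice-relative bin centers (seconds).
#' @return List: `distance_series`, `prechoice_mean`, `prechoice_peak`.
#' @export
distance_metrics <- function(embedded, bin_centers) {
  d <- embedded$early - embedded$late
  series <- sqrt(rowSums(d^2))
  pre <- bin_centers > -5 & bin_centers < 0
  list(distance_series = series,
       prechoice_mean = mean(series[pre]),
       prechoice_peak = max(series[pre]))
}

#' Mean per-component similarity between state trajectories
#'
#' Pearson correlation between the two states' time series on each retained
#' PC, averaged (unweighted) over components. Zero-variance component series
#' are excluded from the mean.
#'
#' @param embedded output of [pca_embed()].
#' @return Mean correlation in `[-1, 1]`.
#' @export
state_similarity <- function(embedded) {
  k <- ncol(embedded$early)
  rs <- vapply(seq_len(k), function(j) {
    x <- embedded$early[, j]; y <- embedded$late[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Bootstrap geometry summary for one group of sessions
#'
#' Runs the full trajectory-geometry protocol: neuron-subset bootstrap,
#' joint PCA embedding, distance and similarity metrics per iteration.
#'
#' @inheritParams build_state_trajectories
#' @param n_components retained PCs (default 6).
#' @return List: `per_iteration` data.frame (prechoice_mean, prechoice_peak,
#'   similarity, variance_explained_total), `distance_series` data.frame
#'   (bin_center_s, mean, sem over iterations).
#' @export
geometry_bootstrap <- function(sessions, subset_fraction = 0.8,
                               n_iterations = 20, n_components = 6,
                               smooth_sigma = 0.15, seed = NULL) {
  pairs <- build_state_trajectories(sessions, subset_fraction, n_iterations,
                                    smooth_sigma, seed = seed)
  bc <- attr(pairs, "bin_centers")
  series <- matrix(NA_real_, length(bc), length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    emb <- pca_embed(pairs[[i]], n_components)
    dm <- distance_metrics(emb, bc)
    series[, i] <<- dm$distance_series
    data.frame(iteration = i, prechoice_mean = dm$prechoice_mean,
               prechoice_peak = dm$prechoice_peak,
               similarity = state_similarity(emb),
               variance_explained_total = sum(emb$variance_explained))
  })
  per_it <- do.call(rbind, rows)
  ds <- data.frame(
    bin_center_s = bc, mean = rowMeans(series),
    sem = apply(series, 1, stats::sd) / sqrt(ncol(series)))
  list(per_iteration = per_it, distance_series = ds)
}
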