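#' Write a session to a directory of plain-text files
#'
#' Layout: `traces.csv` (column 1 `time_s`, one column per neuron),
#' `trials.csv`, `meta.json`, and `truth.csv` when ground-truth tuning labels
#' are present (synthetic sessions only).
#'
#' @param session a `ca_session`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ca_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- data.table::data.table(time_s = session$sample_times)
  tr <- cbind(tr, data.table::as.data.table(t(session$traces)))
  data.table::fwrite(tr, file.path(dir, "traces.csv"))
  trials <- session$trials
  trials_out <- data.frame(
    trial_id = trials$trial_id, stage = trials$stage,
    choice_time_s = trials$choice_time, outcome = trials$outcome,
    correct_rejection = trials$correct_rejection
  )
  data.table::fwrite(trials_out, file.path(dir, "trials.csv"))
  meta <- session$meta
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(session$truth)) {
    data.table::fwrite(session$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @return A `ca_session`.
#' @export
read_session <- function(dir) {
  tr <- data.table::fread(file.path(dir, "traces.csv"))
  sample_times <- tr$time_s
  traces <- t(as.matrix(tr[, -1]))
  trials_in <- data.table::fread(file.path(dir, "trials.csv"))
  trials <- data.frame(
    trial_id = trials_in$trial_id, stage = trials_in$stage,
    choice_time = trials_in$choice_time_s, outcome = trials_in$outcome,
    correct_rejection = trials_in$correct_rejection, stringsAsFactors = FALSE
  )
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  truth <- NULL
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) truth <- as.data.frame(data.table::fread(tf))
  session <- list(traces = traces, sample_times = sample_times, trials = trials,
                  meta = meta, truth = truth)
  class(session) <- "ca_session"
  session
}
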