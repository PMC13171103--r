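#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates a two-group cohort, labels behavioral states, classifies
#' single-neuron tuning (pooled fraction tables with chi-squared group
#' comparisons), quantifies state-trajectory geometry per group, and runs
#' both bootstrap decoders (HMM states, logistic choices) per session,
#' assembling everything into one report. All randomness derives from the
#' master seed, so reruns with the same configuration are byte-identical on
#' disk (per-stage wall-clock goes to `message()` logging, never into the
#' report).
#'
#' @param config_control,config_test group [generator_config()]s.
#' @param n_per_group sessions per group (default 4).
#' @param n_decode_iterations bootstrap iterations per decoder per session
#'   (desk default 200; the full protocol uses 1000).
#' @param n_geometry_iterations neuron-subset bootstrap iterations for the
#'   geometry stage (default 20).
#' @param n_perm permutations for the tuning null (default 1000).
#' @param seed master seed.
#' @param out_dir optional directory; when given, `report.json` is written
#'   there.
#' @param verbose log per-stage progress and timing to the console.
#' @return The report, an S3 list of class `"setshift_report"`.
#' @export
run_pipeline <- function(config_control = generator_config("control"),
                         config_test = generator_config("test"),
                         n_per_group = 4, n_decode_iterations = 200,
                         n_geometry_iterations = 20, n_perm = 1000,
                         seed = 1, out_dir = NULL, verbose = FALSE) {
  log_stage <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
  t_all <- proc.time()[3]

  log_stage("simulate cohort")
  sessions <- generate_cohort(config_control, config_test, n_per_group, seed)
  groups <- vapply(sessions, function(s) s$meta$group, character(1))

  log_stage("behavior labels")
  behavior <- lapply(sessions, function(s) {
    lab <- label_states(s$trials)
    list(mouse_id = s$meta$mouse_id, group = s$meta$group,
         n_trials = lab$n_trials, switch_point = lab$switch_point,
         trials_to_criterion = trials_to_criterion(s$trials))
  })

  log_stage("single-neuron tuning")
  tuning <- lapply(seq_along(sessions), function(i) {
    classify_session(sessions[[i]], n_perm = n_perm,
                     seed = derive_seed(seed, 1000 + i))
  })
  results_by_group <- list(control = tuning[groups == "control"],
                           test = tuning[groups == "test"])
  fractions <- fraction_table(results_by_group)
  chi <- lapply(seq_len(nrow(fractions)), function(i) {
    r <- fractions[i, ]
    tab <- rbind(c(r$n_responsive_control, r$n_total_control - r$n_responsive_control),
                 c(r$n_responsive_test, r$n_total_test - r$n_responsive_test))
    c(list(variable = r$variable), chi_squared_2x2(tab))
  })

  log_stage("population geometry")
  geometry <- lapply(c(control = "control", test = "test"), function(g) {
    geometry_bootstrap(sessions[groups == g],
                       n_iterations = n_geometry_iterations,
                       seed = derive_seed(seed, if (g == "control") 21 else 22))
  })
  geom_tests <- list(
    prechoice_mean = compare_groups(geometry$control$per_iteration$prechoice_mean,
                                    geometry$test$per_iteration$prechoice_mean),
    prechoice_peak = compare_groups(geometry$control$per_iteration$prechoice_peak,
                                    geometry$test$per_iteration$prechoice_peak),
    similarity = compare_groups(geometry$control$per_iteration$similarity,
                                geometry$test$per_iteration$similarity)
  )

  log_stage("HMM state decoding")
  hmm <- lapply(seq_along(sessions), function(i) {
    decode_bootstrap(sessions[[i]], n_iterations = n_decode_iterations,
                     seed = derive_seed(seed, 2000 + i))
  })
  log_stage("GLM choice decoding")
  glm <- lapply(seq_along(sessions), function(i) {
    choice_decode_bootstrap(sessions[[i]], n_iterations = n_decode_iterations,
                            seed = derive_seed(seed, 3000 + i))
  })

  pool_decode <- function(lst, col) {
    lapply(c(control = "control", test = "test"), function(g) {
      v <- unlist(lapply(lst[groups == g], function(d) {
        ok <- d$per_iteration$valid
        d$per_iteration[[col]][ok]
      }))
      v[is.finite(v)]
    })
  }
  hmm_acc <- pool_decode(hmm, "accuracy_heldout")
  hmm_delta <- pool_decode(hmm, "delta_switch")
  glm_acc <- pool_decode(glm, "accuracy")
  summarize <- function(v) list(mean = mean(v), median = stats::median(v),
                                sem = stats::sd(v) / sqrt(length(v)), n = length(v))

  report <- structure(list(
    schema_version = "1.0",
    seed = seed,
    config = list(control = unclass(config_control), test = unclass(config_test),
                  n_per_group = n_per_group,
                  n_decode_iterations = n_decode_iterations,
                  n_geometry_iterations = n_geometry_iterations, n_perm = n_perm),
    behavior = behavior,
    tuning = list(fractions = fractions, chi_squared = chi),
    geometry = list(
      control = list(per_iteration = geometry$control$per_iteration,
                     distance_series = geometry$control$distance_series),
      test = list(per_iteration = geometry$test$per_iteration,
                  distance_series = geometry$test$distance_series),
      tests = geom_tests),
    hmm_decoding = list(
      per_session = lapply(seq_along(hmm), function(i)
        c(list(mouse_id = sessions[[i]]$meta$mouse_id, group = groups[i]),
          hmm[[i]]$summary)),
      group = list(accuracy_heldout = lapply(hmm_acc, summarize),
                   delta_switch = lapply(hmm_delta, summarize),
                   test = compare_groups(hmm_acc$control, hmm_acc$test))),
    glm_decoding = list(
      per_session = lapply(seq_along(glm), function(i)
        c(list(mouse_id = sessions[[i]]$meta$mouse_id, group = groups[i]),
          glm[[i]]$summary)),
      group = list(accuracy = lapply(glm_acc, summarize),
                   test = compare_groups(glm_acc$control, glm_acc$test)))
  ), class = "setshift_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  log_stage(sprintf("pipeline done in %.1f s", proc.time()[3] - t_all))
  report
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic serialization (no timestamps), so identical seeds yield
#' byte-identical report files.
#'
#' @param report a `setshift_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass_recursive(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_recursive)
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else {
    x
  }
}
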