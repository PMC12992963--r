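# End-to-end orchestration: configuration, simulation of a full experiment,
# and the composed analysis (exclusions -> binned means -> grand averages ->
# curve fits -> acquisition metrics -> model comparison -> permutation test).

#' Full pipeline configuration
#'
#' Bundles the per-stage options. Every field is plain data, so a run's
#' configuration can be echoed verbatim alongside its outputs.
#'
#' @param design A [design_config()].
#' @param cohort A [cohort_config()].
#' @param experiment_label Label for simulated trial tables.
#' @param preprocessing List with `timeout_ms` and `outlier_k`.
#' @param fitting List with `init_two`, `init_one`, `compensate` (`"auto"`
#'   applies undershoot compensation only when a grand-average fit yields an
#'   irregular acquired mean; `"always"`/`"never"` force it), `m` (evaluation
#'   point) and `support_range`.
#' @param inference List with `n_perm`, `seed`, `count_sigma`,
#'   `irregular_criterion`, `magnitude_limit`, `alpha`, `n_comparisons`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(),
                            cohort = cohort_config(),
                            experiment_label = "exp1",
                            preprocessing = list(),
                            fitting = list(),
                            inference = list()) {
  preprocessing <- modifyList(list(timeout_ms = 3100, outlier_k = 3),
                              preprocessing)
  fitting <- modifyList(
    list(init_two = default_init_two_prior(),
         init_one = default_init_one_prior(),
         compensate = "auto", m = m_priors(design$priors),
         support_range = c(min(design$priors$short$support),
                           max(design$priors$long$support))),
    fitting)
  inference <- modifyList(
    list(n_perm = 10000L, seed = 1L, count_sigma = TRUE,
         irregular_criterion = "magnitude", magnitude_limit = 10000,
         alpha = 0.05, n_comparisons = 2L),
    inference)
  config <- list(design = design, cohort = cohort,
                 experiment_label = experiment_label,
                 preprocessing = preprocessing, fitting = fitting,
                 inference = inference)
  validate_config(config)
  structure(config, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (or plain list with the same shape).
#' @return The config, invisibly; errors name every offending key.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- c("design", "cohort", "experiment_label", "preprocessing",
            "fitting", "inference")
  missing <- setdiff(need, names(config))
  if (length(missing)) problems <- c(problems, paste("missing key:", missing))
  if (!length(missing)) {
    if (!inherits(config$design, "design_config")) {
      problems <- c(problems, "design: not a design_config")
    }
    if (!inherits(config$cohort, "cohort_config")) {
      problems <- c(problems, "cohort: not a cohort_config")
    }
    for (key in c("timeout_ms", "outlier_k")) {
      v <- config$preprocessing[[key]]
      if (is.null(v) || !is.numeric(v) || v <= 0) {
        problems <- c(problems, sprintf("preprocessing$%s: missing or not a positive number", key))
      }
    }
    if (!isTRUE(config$fitting$compensate %in% c("auto", "always", "never"))) {
      problems <- c(problems, "fitting$compensate: must be one of auto/always/never")
    }
    if (is.null(config$inference$n_perm) || config$inference$n_perm < 1) {
      problems <- c(problems, "inference$n_perm: missing or < 1")
    }
  }
  if (length(problems)) {
    stop(paste0("invalid pipeline configuration:\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  invisible(config)
}

#' Simulate a full counterbalanced experiment
#'
#' Draws counterbalanced per-participant condition assignments, one trial
#' schedule per participant, a cohort of observer parameters, and the trial
#' table -- everything downstream analysis consumes.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed governing all randomness of the run.
#' @param dir Optional output directory; when given, `schedules.csv`,
#'   `cohort.csv` and `trials.csv` are written there (comma-separated, header
#'   row, empty fields for missing values).
#' @return List with `assignments`, `schedules` (list of per-participant
#'   designs), `cohort`, `trials`, `config`, `seed`.
#' @export
run_simulation <- function(config = pipeline_config(), seed = 1L, dir = NULL) {
  validate_config(config)
  set.seed(seed)
  n <- config$cohort$n
  has_cmr <- config$design$cmr_prior != "none"
  assignments <- counterbalance_assignments(n, cmr = has_cmr)
  schedules <- lapply(seq_len(n), function(i) {
    cfg_i <- config$design
    cfg_i$prior_colors <- if (assignments$short_color[i] == "green") {
      c(short = "green", long = "orange")
    } else {
      c(short = "orange", long = "green")
    }
    if (has_cmr) cfg_i$cmr_prior <- assignments$cmr_prior[i]
    generate_schedule(cfg_i, seed = NULL)
  })
  cohort <- sample_cohort(config$cohort, seed = NULL)
  trials <- simulate_experiment(schedules, cohort,
                                experiment_label = config$experiment_label,
                                seed = NULL)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sched_tab <- dplyr::bind_rows(stats::setNames(
      lapply(schedules, tibble::as_tibble), cohort$participant_id),
      .id = "participant_id")
    write.csv(sched_tab, file.path(dir, "schedules.csv"),
              row.names = FALSE, na = "")
    write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE, na = "")
    write_trials(trials, file.path(dir, "trials.csv"))
  }
  list(assignments = assignments, schedules = schedules, cohort = cohort,
       trials = trials, config = config, seed = seed)
}

#' Analyze a trial table (and optionally compare against a control)
#'
#' Composes the full analysis: exclusion flags, outlier removal, binned
#' means, grand averages, per-bin one- and two-prior fits, acquisition
#' metrics (with undershoot compensation and re-adjustment when the policy
#' calls for it), AICc/Akaike-weight model comparison, per-participant fits,
#' and -- when a control table is supplied -- the per-bin permutation test of
#' the divergence difference.
#'
#' @param trials Trial table (schema of [simulate_responses()] plus
#'   `participant_id`).
#' @param config A [pipeline_config()].
#' @param control Optional control-experiment trial table for the permutation
#'   comparison.
#' @return A list of class `timing_report`; see the elements `exclusions`,
#'   `binned`, `grand`, `fits`, `metrics`, `bias`, `model_comparison`,
#'   `participant_metrics`, `permutation`.
#' @export
run_analysis <- function(trials, config = pipeline_config(), control = NULL) {
  validate_config(config)
  .check_trial_schema(trials)
  prep <- function(tab) {
    tab |>
      flag_invalid_trials(timeout_ms = config$preprocessing$timeout_ms) |>
      remove_outliers(k = config$preprocessing$outlier_k) |>
      compute_binned_means()
  }
  flagged <- trials |>
    flag_invalid_trials(timeout_ms = config$preprocessing$timeout_ms) |>
    remove_outliers(k = config$preprocessing$outlier_k)
  binned <- compute_binned_means(flagged)
  grand <- grand_average(binned)

  fit_cfg <- config$fitting
  bins <- sort(unique(grand$bin))
  fits <- list(); metrics <- list(); bias <- list(); comparisons <- list()
  for (b in bins) {
    gb <- grand[grand$bin == b, ]
    f2 <- fit_two_prior(gb, init = fit_cfg$init_two)
    met <- eval_metrics(f2, m = fit_cfg$m, support_range = fit_cfg$support_range)
    compensated <- FALSE
    comp_info <- NULL
    do_comp <- fit_cfg$compensate == "always" ||
      (fit_cfg$compensate == "auto" && (met$irregular_short || met$irregular_long))
    if (do_comp) {
      comp <- compensate_undershoot(gb)
      f2_adj <- fit_two_prior(comp$adjusted, init = fit_cfg$init_two)
      met_adj <- eval_metrics(f2_adj, m = fit_cfg$m,
                              support_range = fit_cfg$support_range)
      readj <- tryCatch(readjust_mu_hat(f2, f2_adj, fit_cfg$support_range),
                        error = function(e) NULL)
      comp_info <- list(bias = comp$bias$bias[comp$bias$bin == b],
                        fit_adjusted = f2_adj, metrics_adjusted = met_adj,
                        mu_hat_readjusted = readj)
      compensated <- TRUE
    }
    key <- paste0("bin", b)
    fits[[key]] <- f2
    metrics[[key]] <- if (compensated) comp_info$metrics_adjusted else met
    metrics[[key]]$compensated <- compensated
    bias[[key]] <- comp_info
    comparisons[[key]] <- compare_models(
      binned, bin = b, init_two = fit_cfg$init_two,
      init_one = fit_cfg$init_one,
      count_sigma = config$inference$count_sigma,
      compensate = compensated)
  }

  permutation <- NULL
  if (!is.null(control)) {
    .check_trial_schema(control)
    binned_control <- prep(control)
    permutation <- lapply(bins, function(b) {
      permutation_test(
        binned_control, binned, bin = b,
        n_perm = config$inference$n_perm,
        seed = config$inference$seed + b,
        compensate = if (isTRUE(metrics[[paste0("bin", b)]]$compensated))
          "subtract" else "none",
        irregular_criterion = config$inference$irregular_criterion,
        magnitude_limit = config$inference$magnitude_limit,
        support_range = fit_cfg$support_range,
        alpha = config$inference$alpha,
        n_comparisons = config$inference$n_comparisons)
    })
    names(permutation) <- paste0("bin", bins)
  }

  structure(
    list(exclusions = exclusion_report(flagged), binned = binned,
         grand = grand, fits = fits, metrics = metrics, bias = bias,
         model_comparison = comparisons,
         participant_metrics = fit_participants(
           binned, init = fit_cfg$init_two, m = fit_cfg$m,
           support_range = fit_cfg$support_range),
         permutation = permutation, config = config),
    class = "timing_report"
  )
}

#' @export
print.timing_report <- function(x, ...) {
  cat("<timing_report>\n")
  for (key in names(x$metrics)) {
    m <- x$metrics[[key]]
    cat(sprintf(
      "  %s: mu_hat short/long = %.1f/%.1f ms (delta %.1f)%s | TR(%g) delta = %.1f ms\n",
      key, m$mu_hat_short, m$mu_hat_long, m$delta_mu_hat,
      if (isTRUE(m$compensated)) " [bias-compensated]" else "",
      m$m_priors, m$delta_t_r_at_m))
    mc <- x$model_comparison[[key]]
    cat(sprintf("      Akaike weights one/two: %.3f/%.3f\n",
                mc$weight_one, mc$weight_two))
    if (!is.null(x$permutation[[key]])) {
      p <- x$permutation[[key]]
      cat(sprintf("      permutation p = %.4g (observed diff %.1f ms)\n",
                  p$p_value, p$observed_diff))
    }
  }
  invisible(x)
}

#' Simulate and analyze a two-experiment comparison
#'
#' Convenience wrapper reproducing the canonical study shape: a control
#' experiment and a test experiment (e.g. with concomitant motor responses
#' and stronger prior separation late in learning) are simulated, analyzed,
#' and compared with the permutation test.
#'
#' @param config_control,config_test [pipeline_config()]s for the two
#'   experiments.
#' @param seed Integer seed; the two simulations use `seed` and `seed + 1`.
#' @return List with the two simulations and the test experiment's
#'   `timing_report` (which contains the permutation results).
#' @export
reproduce_study <- function(config_control = pipeline_config(experiment_label = "control"),
                            config_test = pipeline_config(
                              cohort = cohort_config(merge_lambda = c(0.5, 0.1)),
                              experiment_label = "test"),
                            seed = 1L) {
  sim_control <- run_simulation(config_control, seed = seed)
  sim_test <- run_simulation(config_test, seed = seed + 1L)
  report <- run_analysis(sim_test$trials, config_test,
                         control = sim_control$trials)
  list(control = sim_control, test = sim_test, report = report)
}

#' Read/write trial tables as comma-separated text
#'
#' Missing values are written as empty fields.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   a tibble with the trial-record column types restored.
#' @export
write_trials <- function(trials, path) {
  write.csv(as.data.frame(trials), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- tibble::as_tibble(read.csv(path, na.strings = ""))
  for (col in c("trial_index", "session", "bin", "n_presses")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  for (col in c("cmr_required", "cmr_pressed")) {
    if (col %in% names(out)) out[[col]] <- as.logical(out[[col]])
  }
  if ("lapse_type" %in% names(out)) out$lapse_type <- as.character(out$lapse_type)
  out
}
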