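# Synthetic cohort: participants are simulated as Bayesian observers whose
# acquired prior means may be merged toward a generalized mean (merge_lambda)
# differently in the first and second half of the experiment, with
# Weber-scaled sensory noise, additive motor noise, a constant timing bias,
# and occasional erroneous trials.

#' Population configuration for a synthetic cohort
#'
#' Each observer parameter is drawn from a Gaussian population distribution
#' `c(mean, sd)` (then clipped to its valid range). `merge_lambda` controls
#' prior merging per trial bin: 1 = a single generalized prior at the midpoint
#' of the acquired means, 0 = two fully independent priors.
#'
#' @param n Cohort size.
#' @param mu_hat_short,mu_hat_long Acquired prior means (ms), `c(mean, sd)`.
#' @param merge_lambda Length-2 numeric: population mean merging fraction in
#'   bins 1 and 2.
#' @param merge_lambda_sd Population SD of the merging fractions.
#' @param r_short,r_long Identified shrinkage ratios sigma/w (ms),
#'   `c(mean, sd)`; smaller `r` means stronger central tendency.
#' @param w Weber fraction, `c(mean, sd)`.
#' @param sigma_motor Additive response noise SD (ms), `c(mean, sd)`.
#' @param bias Constant timing bias (ms; negative = undershoot), `c(mean, sd)`.
#' @param lapse_rate Probability of an erroneous trial (scalar, applied to all
#'   observers).
#' @param cmr_lag_mean Mean lag of the concomitant response after the timing
#'   press (ms), `c(mean, sd)` across observers.
#' @param cmr_lag_sd Within-observer SD of that lag (ms, scalar).
#' @param lapse_types Error modes an erroneous trial may take; a subset of
#'   `"no_response"`, `"multiple_press"`, `"cmr_error"`, `"extreme"`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 20L,
                          mu_hat_short = c(750, 40),
                          mu_hat_long = c(1500, 40),
                          merge_lambda = c(0.5, 0.5),
                          merge_lambda_sd = 0.1,
                          r_short = c(1580, 200),
                          r_long = c(1580, 200),
                          w = c(0.15, 0.03),
                          sigma_motor = c(50, 15),
                          bias = c(0, 20),
                          lapse_rate = 0.02,
                          cmr_lag_mean = c(10, 5),
                          cmr_lag_sd = 15,
                          lapse_types = c("no_response", "multiple_press",
                                          "cmr_error", "extreme")) {
  pairs <- list(mu_hat_short = mu_hat_short, mu_hat_long = mu_hat_long,
                r_short = r_short, r_long = r_long, w = w,
                sigma_motor = sigma_motor, bias = bias,
                cmr_lag_mean = cmr_lag_mean)
  for (nm in names(pairs)) {
    v <- pairs[[nm]]
    if (length(v) != 2L || anyNA(v) || v[2] < 0) {
      stop(sprintf("`%s` must be c(mean, sd) with sd >= 0", nm), call. = FALSE)
    }
  }
  if (length(merge_lambda) != 2L || any(merge_lambda < 0) || any(merge_lambda > 1)) {
    stop("`merge_lambda` must give two fractions in [0, 1]", call. = FALSE)
  }
  if (merge_lambda_sd < 0) stop("`merge_lambda_sd` must be >= 0", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate >= 1) {
    stop("`lapse_rate` must be in [0, 1)", call. = FALSE)
  }
  if (cmr_lag_sd < 0) stop("`cmr_lag_sd` must be >= 0", call. = FALSE)
  lapse_types <- match.arg(lapse_types, several.ok = TRUE)
  structure(
    list(n = as.integer(n), mu_hat_short = mu_hat_short,
         mu_hat_long = mu_hat_long, merge_lambda = merge_lambda,
         merge_lambda_sd = merge_lambda_sd, r_short = r_short,
         r_long = r_long, w = w, sigma_motor = sigma_motor, bias = bias,
         lapse_rate = lapse_rate, cmr_lag_mean = cmr_lag_mean,
         cmr_lag_sd = cmr_lag_sd, lapse_types = lapse_types),
    class = "cohort_config"
  )
}

#' Draw a cohort of observer parameter sets
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Tibble with one row per observer: acquired means, per-bin merging
#'   fractions, shrinkage ratios, Weber fraction, motor noise SD, bias, lapse
#'   rate and concomitant-lag parameters.
#' @export
sample_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  draw <- function(p) rnorm(n, p[1], p[2])
  clip01 <- function(x) pmin(1, pmax(0, x))
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    mu_hat_short = draw(config$mu_hat_short),
    mu_hat_long = draw(config$mu_hat_long),
    lambda_bin1 = clip01(rnorm(n, config$merge_lambda[1], config$merge_lambda_sd)),
    lambda_bin2 = clip01(rnorm(n, config$merge_lambda[2], config$merge_lambda_sd)),
    r_short = pmax(1, draw(config$r_short)),
    r_long = pmax(1, draw(config$r_long)),
    w = pmax(0, draw(config$w)),
    sigma_motor = pmax(0, draw(config$sigma_motor)),
    bias = draw(config$bias),
    lapse_rate = rep(config$lapse_rate, n),
    cmr_lag_mean = draw(config$cmr_lag_mean),
    cmr_lag_sd = rep(config$cmr_lag_sd, n)
  )
}

#' Simulate one observer's responses to a schedule
#'
#' Generative reading of the observer model, applied trial by trial: the
#' sensed interval is `t_m ~ N(t_s, (w t_s)^2)` (floored at 1 ms); the timing
#' estimate shrinks `t_m` toward the bin's effective prior mean
#' `(1 - lambda) * mu_hat_p + lambda * (mu_hat_short + mu_hat_long) / 2` with
#' weight `r_p^2 / (r_p^2 + t_m^2)` (`w = 0` disables both noise and
#' shrinkage); the recorded response adds motor noise and the constant bias.
#' With probability `lapse_rate` the trial is instead erroneous: a missing
#' response, a duplicate press, a concomitant-response error, or a grossly
#' mistimed press (type drawn uniformly from the enabled `lapse_types`;
#' concomitant errors are only generated when the schedule contains
#' concomitant-response trials).
#'
#' @param observer One-row data frame (or list) of observer parameters as
#'   produced by [sample_cohort()].
#' @param schedule An `experiment_design` (or any data frame with columns
#'   `trial_index`, `bin`, `prior_label`, `t_s`, `cmr_required`).
#' @param lapse_types Error modes to generate; defaults to all four.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return Tibble with the schedule columns plus `t_r` (ms, `NA` when no
#'   press), `n_presses`, `cmr_pressed`, `cmr_lag` and the generator's
#'   ground-truth `lapse_type` (`NA` for clean trials).
#' @export
simulate_responses <- function(observer, schedule,
                               lapse_types = c("no_response", "multiple_press",
                                               "cmr_error", "extreme"),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- as.list(observer)
  nt <- nrow(schedule)
  stopifnot(nt >= 1L, all(schedule$t_s > 0))
  lapse_types <- match.arg(lapse_types, several.ok = TRUE)
  if (!any(schedule$cmr_required)) {
    lapse_types <- setdiff(lapse_types, "cmr_error")
  }

  lambda <- ifelse(schedule$bin == 1L, obs$lambda_bin1, obs$lambda_bin2)
  mu_p <- ifelse(schedule$prior_label == "short", obs$mu_hat_short, obs$mu_hat_long)
  r_p <- ifelse(schedule$prior_label == "short", obs$r_short, obs$r_long)
  m_gen <- (obs$mu_hat_short + obs$mu_hat_long) / 2
  mu_eff <- (1 - lambda) * mu_p + lambda * m_gen

  if (obs$w > 0) {
    t_m <- pmax(1, rnorm(nt, schedule$t_s, obs$w * schedule$t_s))
    a <- r_p^2 / (r_p^2 + t_m^2)
    est <- a * t_m + (1 - a) * mu_eff
  } else {
    est <- schedule$t_s
  }
  t_r <- pmax(1, est + rnorm(nt, 0, obs$sigma_motor) + obs$bias)

  n_presses <- rep(1L, nt)
  cmr_pressed <- schedule$cmr_required
  cmr_lag <- ifelse(cmr_pressed, rnorm(nt, obs$cmr_lag_mean, obs$cmr_lag_sd),
                    NA_real_)

  lapse_type <- rep(NA_character_, nt)
  is_lapse <- runif(nt) < obs$lapse_rate
  if (any(is_lapse) && length(lapse_types)) {
    lapse_type[is_lapse] <- sample(lapse_types, sum(is_lapse), replace = TRUE)
    i <- which(lapse_type == "no_response")
    t_r[i] <- NA_real_; n_presses[i] <- 0L
    cmr_pressed[i] <- FALSE; cmr_lag[i] <- NA_real_
    i <- which(lapse_type == "multiple_press")
    n_presses[i] <- 2L
    i <- which(lapse_type == "cmr_error")
    cmr_pressed[i] <- !schedule$cmr_required[i]
    cmr_lag[i] <- ifelse(cmr_pressed[i],
                         rnorm(length(i), obs$cmr_lag_mean, obs$cmr_lag_sd),
                         NA_real_)
    i <- which(lapse_type == "extreme")
    t_r[i] <- t_r[i] * sample(c(0.3, 2), length(i), replace = TRUE)
  }

  out <- tibble::as_tibble(schedule)
  out$t_r <- t_r
  out$n_presses <- n_presses
  out$cmr_pressed <- cmr_pressed
  out$cmr_lag <- cmr_lag
  out$lapse_type <- lapse_type
  out
}

#' Simulate a single trial
#'
#' Scalar convenience wrapper around [simulate_responses()].
#'
#' @inheritParams simulate_responses
#' @param trial One-row trial plan (`prior_label`, `t_s`, `cmr_required`).
#' @param bin_index Trial bin (1 or 2) selecting the merging fraction.
#' @return One-row tibble (see [simulate_responses()]).
#' @export
simulate_response <- function(observer, trial, bin_index = 1L, seed = NULL) {
  trial <- tibble::as_tibble(as.list(trial)[c("prior_label", "t_s", "cmr_required")])
  trial$bin <- as.integer(bin_index)
  trial$trial_index <- 1L
  simulate_responses(observer, trial, seed = seed)
}

#' Simulate a full multi-participant experiment
#'
#' @param designs A single `experiment_design` shared by all participants, or
#'   a list of designs, one per cohort row (e.g. from counterbalanced
#'   configurations).
#' @param cohort Tibble of observer parameters from [sample_cohort()].
#' @param experiment_label Label stored in the output (e.g. `"exp1"`).
#' @param lapse_types Passed to [simulate_responses()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return Tibble of trial records: one row per participant x trial, with
#'   `participant_id` and `experiment_label` prepended to the
#'   [simulate_responses()] columns.
#' @export
simulate_experiment <- function(designs, cohort, experiment_label = "exp1",
                                lapse_types = c("no_response", "multiple_press",
                                                "cmr_error", "extreme"),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  if (inherits(designs, "data.frame")) designs <- list(designs)
  if (length(designs) == 1L) designs <- rep(designs, n)
  stopifnot(length(designs) == n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- simulate_responses(cohort[i, ], designs[[i]], lapse_types = lapse_types)
    rec <- tibble::add_column(rec,
                              participant_id = cohort$participant_id[i],
                              experiment_label = experiment_label,
                              .before = 1L)
    out[[i]] <- rec
  }
  dplyr::bind_rows(out)
}
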