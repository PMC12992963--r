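# Trial-schedule generation for the alternating two-prior timing task:
# 640 trials (40 x 16 sessions), the two priors strictly alternating and
# bound to stimulus colors, 160 trials per prior within each 320-trial bin.

#' Design configuration for a two-prior timing experiment
#'
#' @param priors Named list with `prior_spec` elements `short` and `long`.
#' @param n_trials Total trials (default 640); must be even and is split into
#'   two equal trial bins.
#' @param trials_per_session Trials per session (default 40); must divide
#'   `n_trials`.
#' @param prior_colors Named character vector mapping prior labels to stimulus
#'   colors (a bijection within one design).
#' @param cmr_prior Which prior requires a concomitant motor response (an
#'   additional simultaneous press by another effector): `"none"`, `"short"`
#'   or `"long"`.
#' @param sampling `"balanced"` draws each support value equally often per
#'   prior per bin (32 times each in the default design) in random order;
#'   `"iid"` samples uniformly with replacement.
#' @param first_prior Prior of trial 1; `NULL` (default) picks at random so
#'   the starting prior varies with the seed.
#' @return A list of class `design_config`.
#' @export
design_config <- function(priors = default_priors(),
                          n_trials = 640L,
                          trials_per_session = 40L,
                          prior_colors = c(short = "green", long = "orange"),
                          cmr_prior = c("none", "short", "long"),
                          sampling = c("balanced", "iid"),
                          first_prior = NULL) {
  cmr_prior <- match.arg(cmr_prior)
  sampling <- match.arg(sampling)
  stopifnot(all(c("short", "long") %in% names(priors)),
            all(c("short", "long") %in% names(prior_colors)))
  if (anyDuplicated(prior_colors)) {
    stop("`prior_colors` must map the two priors to distinct colors",
         call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  trials_per_session <- as.integer(trials_per_session)
  if (n_trials %% 2L != 0L) {
    stop("strict prior alternation requires an even `n_trials`", call. = FALSE)
  }
  if (n_trials %% trials_per_session != 0L) {
    stop("`trials_per_session` must divide `n_trials`", call. = FALSE)
  }
  if ((n_trials / 2L) %% 2L != 0L) {
    stop("`n_trials`/2 must be even so each bin holds both priors equally",
         call. = FALSE)
  }
  per_prior_bin <- n_trials / 4L  # trials per prior within each half
  if (sampling == "balanced") {
    for (p in c("short", "long")) {
      k <- length(priors[[p]]$support)
      if (per_prior_bin %% k != 0L) {
        stop(sprintf(
          "balanced sampling needs %d trials per prior per bin divisible by %d support values",
          per_prior_bin, k), call. = FALSE)
      }
    }
  }
  if (!is.null(first_prior)) first_prior <- match.arg(first_prior, c("short", "long"))
  structure(
    list(priors = priors, n_trials = n_trials,
         trials_per_session = trials_per_session,
         prior_colors = prior_colors, cmr_prior = cmr_prior,
         sampling = sampling, first_prior = first_prior),
    class = "design_config"
  )
}

#' Generate a trial schedule
#'
#' Produces the full trial plan: the two priors alternate strictly from trial
#' to trial, each bound to its stimulus color; target intervals are drawn from
#' the active prior's support (balanced within each half of the experiment by
#' default); the concomitant-response requirement follows the configured
#' prior.
#'
#' @param config A [design_config()].
#' @param seed Integer seed making the schedule reproducible; `NULL` uses the
#'   current RNG state (for callers that manage their own stream).
#' @return A tibble of class `experiment_design` with one row per trial:
#'   `trial_index`, `session`, `bin`, `prior_label`, `color`, `t_s`,
#'   `cmr_required`. The configuration and seed are attached as attributes
#'   `config` and `seed`.
#' @export
generate_schedule <- function(config = design_config(), seed = NULL) {
  stopifnot(inherits(config, "design_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  half <- n / 2L

  first <- config$first_prior %||% sample(c("short", "long"), 1L)
  labels <- rep_len(if (first == "short") c("short", "long") else c("long", "short"), n)

  t_s <- numeric(n)
  for (b in 1:2) {
    in_bin <- seq.int((b - 1L) * half + 1L, b * half)
    for (p in c("short", "long")) {
      idx <- in_bin[labels[in_bin] == p]
      sup <- config$priors[[p]]$support
      t_s[idx] <- if (config$sampling == "balanced") {
        sample(rep(sup, length.out = length(idx)))
      } else {
        sample(sup, length(idx), replace = TRUE)
      }
    }
  }

  out <- tibble::tibble(
    trial_index = seq_len(n),
    session = as.integer((seq_len(n) - 1L) %/% config$trials_per_session + 1L),
    bin = as.integer((seq_len(n) - 1L) %/% half + 1L),
    prior_label = labels,
    color = unname(config$prior_colors[labels]),
    t_s = t_s,
    cmr_required = labels == config$cmr_prior
  )
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("experiment_design", class(out))
  out
}

#' Counterbalance condition combinations across participants
#'
#' Two binary condition factors are counterbalanced: which prior is shown in
#' green (vs orange), and which color carries the concomitant motor response.
#' Their four combinations are assigned in equal numbers; when `n` is not a
#' multiple of four the assignment is maximally balanced and a warning is
#' raised.
#'
#' @param n_participants Number of participants.
#' @param cmr Logical; if `FALSE` (a control experiment without concomitant
#'   responses) only the two prior-color pairings are balanced and
#'   `cmr_prior` is `"none"` throughout.
#' @return Tibble with one row per participant: `participant_id`,
#'   `short_color`, `cmr_color`, `cmr_prior`.
#' @export
counterbalance_assignments <- function(n_participants, cmr = TRUE) {
  n_participants <- as.integer(n_participants)
  stopifnot(n_participants >= 1L)
  combos <- if (cmr) {
    expand.grid(short_color = c("green", "orange"),
                cmr_color = c("green", "orange"),
                stringsAsFactors = FALSE)
  } else {
    data.frame(short_color = c("green", "orange"),
               cmr_color = NA_character_)
  }
  if (n_participants %% nrow(combos) != 0L) {
    warning(sprintf(
      "%d participants cannot be split evenly over %d condition combinations; using a maximally balanced assignment",
      n_participants, nrow(combos)))
  }
  idx <- rep_len(seq_len(nrow(combos)), n_participants)
  out <- tibble::as_tibble(combos[idx, , drop = FALSE])
  out$participant_id <- sprintf("P%02d", seq_len(n_participants))
  out$cmr_prior <- if (cmr) {
    ifelse(out$cmr_color == out$short_color, "short", "long")
  } else {
    "none"
  }
  out[, c("participant_id", "short_color", "cmr_color", "cmr_prior")]
}

#' Write a schedule as tabular text
#'
#' Comma-separated trial table preceded by `#`-prefixed metadata comment
#' lines (seed, counts, prior/color/CMR pairings).
#'
#' @param design An `experiment_design` from [generate_schedule()].
#' @param path Output file path.
#' @export
write_schedule <- function(design, path) {
  config <- attr(design, "config")
  meta <- c(
    sprintf("# seed: %s", attr(design, "seed") %||% "NA"),
    sprintf("# n_trials: %d", config$n_trials),
    sprintf("# prior_colors: short=%s long=%s",
            config$prior_colors[["short"]], config$prior_colors[["long"]]),
    sprintf("# cmr_prior: %s", config$cmr_prior),
    sprintf("# sampling: %s", config$sampling)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(as.data.frame(design), con, row.names = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
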