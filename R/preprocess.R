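# Trial exclusion and binned means.
#
# Exclusion proceeds in two ordered, idempotent passes: (1) validity flags
# for erroneous responses (no/late press, duplicate presses, concomitant-
# response errors); (2) a single-pass +-3 SD outlier rule per participant x
# trial bin x target interval, computed over valid trials only. Means are
# then taken per participant x bin x prior x T_S, and grand averages across
# participants.

.trial_cols <- c("participant_id", "trial_index", "bin", "prior_label",
                 "t_s", "t_r", "n_presses", "cmr_required", "cmr_pressed")

.check_trial_schema <- function(table, cols = .trial_cols) {
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop(sprintf("trial table is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(table)
}

#' Flag erroneous trials
#'
#' A trial is invalid if it has no timing press, the press falls after the
#' trial timeout, the same button was pressed two or more times, or the
#' concomitant response is missing when required / present when not. Rows are
#' preserved; flags are added.
#'
#' @param table Trial table with the [simulate_responses()] column schema.
#' @param timeout_ms Response window after the final reference stimulus (ms);
#'   a press with `t_r > t_s + timeout_ms` counts as no response in time.
#' @return The table with logical `valid` and character `invalid_reason`
#'   (`NA` for valid rows) columns appended.
#' @seealso [exclusion_report()] for per-participant tallies by reason.
#' @export
flag_invalid_trials <- function(table, timeout_ms = 3100) {
  .check_trial_schema(table)
  reason <- dplyr::case_when(
    table$n_presses >= 2L ~ "multiple_press",
    table$n_presses == 0L | is.na(table$t_r) ~ "no_response",
    table$t_r <= 0 ~ "nonpositive_response",
    table$t_r > table$t_s + timeout_ms ~ "late_response",
    table$cmr_required & !table$cmr_pressed ~ "cmr_missing",
    !table$cmr_required & table$cmr_pressed ~ "cmr_extra",
    .default = NA_character_
  )
  table$invalid_reason <- reason
  table$valid <- is.na(reason)
  table
}

#' Tally exclusions per participant and reason
#'
#' @param table A table that has passed [flag_invalid_trials()] (and
#'   optionally [remove_outliers()]).
#' @return Tibble of counts per `participant_id` x exclusion reason
#'   (including `"outlier"` when present).
#' @export
exclusion_report <- function(table) {
  stopifnot("valid" %in% names(table))
  tab <- table
  tab$reason <- tab$invalid_reason
  if ("outlier" %in% names(tab)) {
    tab$reason[is.na(tab$reason) & tab$outlier] <- "outlier"
  }
  tab <- tab[!is.na(tab$reason), c("participant_id", "reason")]
  dplyr::count(tab, .data$participant_id, .data$reason, name = "n_excluded")
}

#' Flag response-time outliers
#'
#' Single-pass rule: within each participant x trial bin x target interval,
#' a valid trial is an outlier when its response lies strictly outside
#' mean +- `k` x SD (n - 1 SD; boundary values are retained), with mean and SD
#' computed over the valid trials of that cell. Cells with fewer than three
#' valid trials are left unflagged with a warning. Invalid trials are never
#' flagged (they are already excluded).
#'
#' @param table Output of [flag_invalid_trials()].
#' @param k Width of the rejection band in SD units (default 3).
#' @return The table with a logical `outlier` column appended.
#' @export
remove_outliers <- function(table, k = 3) {
  .check_trial_schema(table, c(.trial_cols, "valid"))
  grp <- interaction(table$participant_id, table$bin, table$t_s, drop = TRUE)
  m <- stats::ave(ifelse(table$valid, table$t_r, NA), grp,
                  FUN = function(x) mean(x, na.rm = TRUE))
  s <- stats::ave(ifelse(table$valid, table$t_r, NA), grp,
                  FUN = function(x) sd(x, na.rm = TRUE))
  n_valid <- stats::ave(as.numeric(table$valid), grp, FUN = sum)
  small <- n_valid < 3
  if (any(small & table$valid)) {
    warning(sprintf(
      "%d cell(s) have fewer than 3 valid trials; no outlier flagging there",
      length(unique(grp[small]))))
  }
  out <- table$valid & !small & !is.na(s) & s > 0 &
    abs(table$t_r - m) > k * s
  table$outlier <- ifelse(is.na(out), FALSE, out)
  table
}

#' Per-participant binned mean responses
#'
#' Averages the surviving responses across every half of the experiment
#' (trial bin), separately per prior and target interval: the participant's
#' mean-response profile that all curve fitting operates on.
#'
#' @param table Output of [remove_outliers()].
#' @return Tibble with one row per participant x bin x prior x `t_s`:
#'   `t_r_mean`, `n_used`, `n_excluded` (an `experiment_label` column is
#'   carried through when present).
#' @export
compute_binned_means <- function(table) {
  .check_trial_schema(table, c(.trial_cols, "valid", "outlier"))
  keys <- c("participant_id",
            intersect("experiment_label", names(table)),
            "bin", "prior_label", "t_s")
  kept <- table$valid & !table$outlier
  out <- table |>
    dplyr::mutate(.kept = kept) |>
    dplyr::summarise(
      t_r_mean = mean(.data$t_r[.data$.kept]),
      n_used = sum(.data$.kept),
      n_excluded = dplyr::n() - sum(.data$.kept),
      .by = dplyr::all_of(keys)
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  if (any(out$n_used == 0L)) {
    bad <- out[out$n_used == 0L, ][1, ]
    stop(sprintf(
      "all trials excluded in cell participant=%s bin=%d prior=%s t_s=%g",
      bad$participant_id, bad$bin, bad$prior_label, bad$t_s), call. = FALSE)
  }
  out
}

#' Grand-average mean responses across participants
#'
#' Unweighted mean of the per-participant binned means, used to stabilize
#' curve fits against idiosyncratic individual response patterns.
#'
#' @param binned Output of [compute_binned_means()] (one experiment).
#' @return Tibble with one row per bin x prior x `t_s`: `t_r_mean`,
#'   `n_participants`.
#' @export
grand_average <- function(binned) {
  stopifnot(all(c("participant_id", "bin", "prior_label", "t_s", "t_r_mean")
                %in% names(binned)))
  counts <- dplyr::count(binned, .data$bin, .data$prior_label, .data$t_s)
  n_per_cell <- unique(counts$n)
  n_cells <- dplyr::n_distinct(binned$bin, binned$prior_label, binned$t_s)
  per_participant <- dplyr::count(binned, .data$participant_id)
  if (length(n_per_cell) != 1L || any(per_participant$n != n_cells)) {
    stop("ragged participation: every participant must contribute to every (bin, prior, t_s) cell",
         call. = FALSE)
  }
  binned |>
    dplyr::summarise(t_r_mean = mean(.data$t_r_mean),
                     n_participants = dplyr::n(),
                     .by = c("bin", "prior_label", "t_s")) |>
    dplyr::arrange(.data$bin, .data$prior_label, .data$t_s)
}
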