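# Small hand-built trial tables with planted defects.
planted_table <- function() {
  tibble::tibble(
    participant_id = "P01",
    trial_index = 1:8,
    bin = 1L,
    prior_label = rep(c("short", "long"), 4),
    t_s = rep(c(750, 1500), 4),
    t_r = c(760, 1490, NA, 1500, 755, 6000, 740, 1505),
    n_presses = c(1L, 1L, 0L, 2L, 1L, 1L, 1L, 1L),
    cmr_required = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    cmr_pressed = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

test_that("erroneous trials are flagged with the right reasons", {
  flagged <- flag_invalid_trials(planted_table())
  expect_equal(flagged$invalid_reason,
               c(NA, NA, "no_response", "multiple_press", "cmr_missing",
                 "late_response", "cmr_extra", NA))
  expect_equal(flagged$valid, is.na(flagged$invalid_reason))
  # all-clean table: zero flags
  clean <- planted_table()[c(1, 2, 8), ]
  expect_true(all(flag_invalid_trials(clean)$valid))
  expect_error(flag_invalid_trials(planted_table()[, -6]),
               "missing required column")
  rep <- exclusion_report(flagged)
  expect_equal(sum(rep$n_excluded), 5)
})

test_that("a planted extreme value is the only outlier flagged", {
  set.seed(31)
  base <- rnorm(31, 900, 10)
  extreme <- mean(base) + 6 * sd(base)
  tab <- tibble::tibble(
    participant_id = "P01", trial_index = 1:32, bin = 1L,
    prior_label = "short", t_s = 900, t_r = c(base, extreme),
    n_presses = 1L, cmr_required = FALSE, cmr_pressed = FALSE)
  out <- remove_outliers(flag_invalid_trials(tab))
  expect_equal(which(out$outlier), 32L)
})

test_that("outlier rule keeps boundary values and degenerate cells", {
  # constant values: SD = 0, nothing flagged
  tab <- tibble::tibble(
    participant_id = "P01", trial_index = 1:10, bin = 1L,
    prior_label = "short", t_s = 750, t_r = 750,
    n_presses = 1L, cmr_required = FALSE, cmr_pressed = FALSE)
  expect_false(any(remove_outliers(flag_invalid_trials(tab))$outlier))
  # a value exactly at mean + 3 SD (of the cell including it) is retained
  base <- c(740, 745, 750, 750, 755, 760, 748, 752, 751, 749)
  v <- uniroot(function(v) {
    x <- c(base, v); v - mean(x) - 3 * sd(x)
  }, c(760, 2000))$root
  tab2 <- tibble::tibble(
    participant_id = "P01", trial_index = 1:11, bin = 1L,
    prior_label = "short", t_s = 750, t_r = c(base, v),
    n_presses = 1L, cmr_required = FALSE, cmr_pressed = FALSE)
  out <- remove_outliers(flag_invalid_trials(tab2))
  expect_false(out$outlier[11])
  # nudging it outside the closed interval flags it
  tab3 <- tab2
  tab3$t_r[11] <- v * 1.05
  expect_true(remove_outliers(flag_invalid_trials(tab3))$outlier[11])
})

test_that("cells with fewer than three valid trials warn and stay unflagged", {
  tab <- tibble::tibble(
    participant_id = "P01", trial_index = 1:2, bin = 1L,
    prior_label = "short", t_s = 450, t_r = c(450, 800),
    n_presses = 1L, cmr_required = FALSE, cmr_pressed = FALSE)
  expect_warning(out <- remove_outliers(flag_invalid_trials(tab)),
                 "fewer than 3")
  expect_false(any(out$outlier))
})

test_that("outlier statistics use valid trials only", {
  # an invalid huge value must not widen the band for the valid ones
  set.seed(32)
  good <- rnorm(20, 900, 10)
  tab <- tibble::tibble(
    participant_id = "P01", trial_index = 1:22, bin = 1L,
    prior_label = "short", t_s = 900,
    t_r = c(good, mean(good) + 5 * sd(good), 1e6),
    n_presses = c(rep(1L, 21), 2L),
    cmr_required = FALSE, cmr_pressed = FALSE)
  out <- remove_outliers(flag_invalid_trials(tab))
  expect_true(out$outlier[21])   # caught against the valid-trial band
  expect_false(out$outlier[22])  # invalid, not additionally an outlier
})

test_that("binned means have the design's cell structure", {
  cfg <- pipeline_config(cohort = fixed_cohort_config(n = 2, w = 0,
                                                      sigma_motor = 0))
  trials <- run_simulation(cfg, seed = 21)$trials
  binned <- prep_trials(trials)
  expect_equal(nrow(binned), 2 * 2 * 2 * 5)  # participants x bins x priors x t_s
  expect_true(all(binned$n_used + binned$n_excluded == 32))
  # noise-free: every binned mean equals its target interval
  expect_equal(binned$t_r_mean, binned$t_s)
})

test_that("binned means shift by the bias when w = 0", {
  cfg <- pipeline_config(cohort = fixed_cohort_config(n = 2, w = 0,
                                                      sigma_motor = 0,
                                                      bias = -50))
  binned <- prep_trials(run_simulation(cfg, seed = 22)$trials)
  expect_equal(binned$t_r_mean, binned$t_s - 50)
})

test_that("an emptied cell raises a named error", {
  tab <- planted_table()[c(1, 2, 8), ]
  tab$n_presses[tab$t_s == 750] <- 2L
  flagged <- suppressWarnings(remove_outliers(flag_invalid_trials(tab)))
  expect_error(suppressWarnings(compute_binned_means(flagged)),
               "participant=P01.*t_s=750")
})

test_that("exclusion flagging is idempotent and excluded rows carry no weight", {
  cfg <- pipeline_config(cohort = fixed_cohort_config(n = 4, lapse_rate = 0.1))
  trials <- run_simulation(cfg, seed = 23)$trials
  f1 <- remove_outliers(flag_invalid_trials(trials))
  f2 <- remove_outliers(flag_invalid_trials(f1))
  expect_equal(f1$valid, f2$valid)
  expect_equal(f1$outlier, f2$outlier)
  b_all <- compute_binned_means(f1)
  b_kept <- compute_binned_means(f1[f1$valid & !f1$outlier, ])
  expect_equal(b_all$t_r_mean, b_kept$t_r_mean)
})

test_that("grand averages match brute-force tabulation and reject ragged input", {
  cfg <- pipeline_config(cohort = cohort_config(n = 5))
  binned <- prep_trials(suppressWarnings(run_simulation(cfg, seed = 24)$trials))
  g <- grand_average(binned)
  # brute-force oracle
  key <- paste(binned$bin, binned$prior_label, binned$t_s)
  expected <- tapply(binned$t_r_mean, key, mean)
  expect_equal(g$t_r_mean,
               as.numeric(expected[paste(g$bin, g$prior_label, g$t_s)]))
  expect_true(all(g$n_participants == 5))
  # single participant: grand average is that participant's profile
  one <- binned[binned$participant_id == "P01", ]
  expect_equal(grand_average(one)$t_r_mean,
               one[order(one$bin, one$prior_label, one$t_s), ]$t_r_mean)
  # symmetry: profiles v and 2 t_s - v average to t_s
  mirrored <- dplyr::bind_rows(one, dplyr::mutate(
    one, participant_id = "P99", t_r_mean = 2 * t_s - t_r_mean))
  gm <- grand_average(mirrored)
  expect_equal(gm$t_r_mean, gm$t_s)
  expect_error(grand_average(binned[-1, ]), "ragged")
})
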