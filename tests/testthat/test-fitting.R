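test_that("noise-free two-prior data are recovered to optimizer tolerance", {
  cases <- list(c(750, 1500, 1580, 1580),
                c(700, 1400, 800, 2400),
                c(950, 1550, 3000, 1200))
  for (ps in cases) {
    pts <- make_curve_points(ps[1], ps[2], ps[3], ps[4])
    fit <- fit_two_prior(pts)
    expect_true(fit$converged)
    expect_equal(fit$mu_short, ps[1], tolerance = 1e-3)
    expect_equal(fit$mu_long, ps[2], tolerance = 1e-3)
    expect_equal(fit$r_short, ps[3], tolerance = 1e-2)
    expect_equal(fit$r_long, ps[4], tolerance = 1e-2)
    expect_lt(fit$rss, 1e-6)
    # the fitted curve reproduces the reported rss on the input points
    res <- pts$t_r_mean - predict(fit, pts$t_s, pts$prior_label)
    expect_equal(sum(res^2), fit$rss)
  }
})

test_that("one-prior model recovers generalized-prior data and respects nesting", {
  grid <- c(seq(450, 1050, 150), seq(1200, 1800, 150))
  pts1 <- tibble::tibble(
    prior_label = rep(c("short", "long"), each = 5), t_s = grid,
    t_r_mean = predict_mean_response(grid, 1125, sigma = 454 / 0.15, w = 1))
  f1 <- fit_one_prior(pts1)
  expect_equal(f1$mu_wide, 1125, tolerance = 1e-3)
  expect_lt(f1$rss, 1e-6)
  # the two-prior model nests the one-prior case
  f2 <- fit_two_prior(pts1)
  expect_equal(f2$mu_short, 1125, tolerance = 1)
  expect_equal(f2$mu_long, 1125, tolerance = 1)
  # on genuinely two-prior data, the one-prior rss is strictly larger
  pts2 <- make_curve_points()
  expect_gt(fit_one_prior(pts2)$rss, fit_two_prior(pts2)$rss)
  # nesting holds on random noisy data too
  set.seed(41)
  for (i in 1:5) {
    noisy <- pts2
    noisy$t_r_mean <- noisy$t_r_mean + rnorm(10, 0, 40)
    expect_gte(fit_one_prior(noisy)$rss + 1e-8, fit_two_prior(noisy)$rss)
  }
})

test_that("identified quantities are invariant to initial values; nominal sigma/w are not", {
  set.seed(42)
  pts <- make_curve_points()
  pts$t_r_mean <- pts$t_r_mean + rnorm(10, 0, 25)
  ref <- fit_two_prior(pts)
  inits <- list(
    list(mu_short = 600, mu_long = 1200, sigma_short = 100, sigma_long = 500, w = 0.15),
    list(mu_short = 1125, mu_long = 1125, sigma_short = 454, sigma_long = 454, w = 0.05),
    list(mu_short = 2000, mu_long = 400, sigma_short = 50, sigma_long = 50, w = 0.30))
  for (init in inits) {
    alt <- fit_two_prior(pts, init = init)
    expect_equal(alt$mu_short, ref$mu_short, tolerance = 1e-6)
    expect_equal(alt$mu_long, ref$mu_long, tolerance = 1e-6)
    expect_equal(alt$rss, ref$rss, tolerance = 1e-6)
    expect_equal(alt$r_short, ref$r_short, tolerance = 1e-4)
    # curve evaluations identical
    expect_equal(predict(alt, 1125, "short"), predict(ref, 1125, "short"),
                 tolerance = 1e-6)
  }
  # the nominal sigma report scales with the (arbitrary) initial w
  alt_w <- fit_two_prior(pts, init = modifyList(default_init_two_prior(),
                                                list(w = 0.30)))
  expect_equal(alt_w$sigma_short, 2 * ref$sigma_short, tolerance = 1e-6)
  expect_equal(alt_w$w, 0.30)
})

test_that("degenerate and underdetermined inputs raise typed errors", {
  grid <- c(seq(450, 1050, 150), seq(1200, 1800, 150))
  unity <- tibble::tibble(prior_label = rep(c("short", "long"), each = 5),
                          t_s = grid, t_r_mean = grid)
  expect_error(fit_two_prior(unity), class = "priortime_unidentifiable")
  expect_error(fit_one_prior(unity), class = "priortime_unidentifiable")
  few <- tibble::tibble(prior_label = c("short", "short", "long", "long"),
                        t_s = c(750, 750, 1200, 1500),
                        t_r_mean = c(780, 790, 1190, 1450))
  expect_error(fit_two_prior(few), "at least 2 distinct")
  expect_error(fit_two_prior(unity[, -1][0, ]), "missing column")
})

test_that("acquisition metrics evaluate both branches at the generalized mean", {
  fit <- two_prior_fit(mu_short = 750, mu_long = 1500,
                       sigma_short = 237, sigma_long = 237, w = 0.15)
  met <- eval_metrics(fit)
  # oracle: direct curve evaluation at 1125 ms
  expect_equal(met$t_r_at_m_short,
               predict_mean_response(1125, 750, 237, 0.15))
  expect_equal(met$t_r_at_m_long,
               predict_mean_response(1125, 1500, 237, 0.15))
  expect_gt(met$delta_t_r_at_m, 0)
  expect_equal(met$delta_mu_hat, 750)
  # the acquired means equal the unity-line intersections exactly
  expect_identical(met$mu_hat_short, unity_intersection(fit$mu_short, 237, 0.15))
  expect_identical(met$mu_hat_long, unity_intersection(fit$mu_long, 237, 0.15))
  expect_false(met$irregular_short || met$irregular_long)
  # merged fit: both deltas vanish
  merged <- eval_metrics(two_prior_fit(1125, 1125, 454, 454, 0.15))
  expect_equal(merged$delta_t_r_at_m, 0)
  expect_equal(merged$delta_mu_hat, 0)
  # an implausible acquired mean is flagged, never clipped
  irr <- eval_metrics(two_prior_fit(-50635.5, 1500, 237, 237, 0.15))
  expect_true(irr$irregular_short)
  expect_false(irr$irregular_long)
  expect_equal(irr$mu_hat_short, -50635.5)
  expect_error(eval_metrics(two_prior_fit(750, 1500, 237, 237, 0.15,
                                          converged = FALSE)),
               "converge")
})

test_that("undershoot compensation recovers a constant bias", {
  grid <- c(seq(450, 1050, 150), seq(1200, 1800, 150))
  grand0 <- tibble::tibble(bin = 1L,
                           prior_label = rep(c("short", "long"), each = 5),
                           t_s = grid, t_r_mean = grid)
  comp0 <- compensate_undershoot(grand0)
  expect_equal(comp0$bias$bias, 0)
  expect_equal(comp0$adjusted$t_r_mean, grand0$t_r_mean)
  grand50 <- dplyr::mutate(grand0, t_r_mean = t_s - 50)
  comp50 <- compensate_undershoot(grand50)
  expect_equal(comp50$bias$bias, -50)
  expect_equal(comp50$adjusted$t_r_mean, grand50$t_s)
  # generator oracle: cohort with a -48 ms bias and no shrinkage (w = 0)
  cfg <- pipeline_config(cohort = fixed_cohort_config(n = 20, w = 0,
                                                      bias = -48))
  grand <- grand_average(prep_trials(run_simulation(cfg, seed = 51)$trials))
  comp <- compensate_undershoot(grand)
  expect_equal(comp$bias$bias, c(-48, -48), tolerance = 3 / 48)
})

test_that("mu_hat re-adjustment pins the long prior to its original-fit value", {
  pts <- make_curve_points()
  fit_sub <- fit_two_prior(pts)
  # identical fits: identity adjustment
  adj0 <- readjust_mu_hat(fit_sub, fit_sub)
  expect_equal(as.vector(adj0), c(fit_sub$mu_short, fit_sub$mu_long))
  expect_equal(attr(adj0, "d"), 0)
  # biased data: the original fit is distorted; compensation restores the
  # generator curve and re-adjustment maps it back to the original scale
  biased <- dplyr::mutate(pts, t_r_mean = t_r_mean - 60)
  fit_orig <- fit_two_prior(biased)
  adj <- readjust_mu_hat(fit_orig, fit_sub)
  expect_equal(unname(adj[2]), fit_orig$mu_long)
  expect_equal(attr(adj, "d"), fit_sub$mu_long - fit_orig$mu_long)
  # irregular long-prior means abort the adjustment
  bad <- two_prior_fit(750, 25000, 237, 237, 0.15)
  expect_error(readjust_mu_hat(bad, fit_sub), "irregular")
})

test_that("per-participant fits cover every participant x bin cell", {
  cfg <- pipeline_config(cohort = fixed_cohort_config(n = 4))
  binned <- prep_trials(run_simulation(cfg, seed = 52)$trials)
  pm <- fit_participants(binned)
  expect_equal(nrow(pm), 8)
  expect_true(all(is.finite(pm$delta_t_r_at_m)))
  expect_setequal(unique(pm$bin), c(1L, 2L))
})
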