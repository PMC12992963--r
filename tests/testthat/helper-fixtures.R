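# Shared fixture builders. Everything is generated in code at test time.

# Noise-free mean-response points from known branch parameters.
# r_* are the identified sigma/w ratios (points are built with w = 1,
# sigma = r, which pins the same curve).
make_curve_points <- function(mu_short = 750, mu_long = 1500,
                              r_short = 1580, r_long = 1580) {
  grid_s <- seq(450, 1050, by = 150)
  grid_l <- seq(1200, 1800, by = 150)
  tibble::tibble(
    prior_label = rep(c("short", "long"), each = 5),
    t_s = c(grid_s, grid_l),
    t_r_mean = c(
      predict_mean_response(grid_s, mu_short, sigma = r_short, w = 1),
      predict_mean_response(grid_l, mu_long, sigma = r_long, w = 1))
  )
}

# Cohort with identical observers (population SDs zero).
fixed_cohort_config <- function(n = 20, mu_short = 750, mu_long = 1500,
                                lambda = c(0, 0), r = 1580, w = 0.15,
                                sigma_motor = 50, bias = 0, lapse_rate = 0) {
  cohort_config(
    n = n, mu_hat_short = c(mu_short, 0), mu_hat_long = c(mu_long, 0),
    merge_lambda = lambda, merge_lambda_sd = 0,
    r_short = c(r, 0), r_long = c(r, 0), w = c(w, 0),
    sigma_motor = c(sigma_motor, 0), bias = c(bias, 0),
    lapse_rate = lapse_rate, cmr_lag_mean = c(10, 0))
}

# flag -> outlier-screen -> binned means
prep_trials <- function(trials) {
  trials |>
    flag_invalid_trials() |>
    remove_outliers() |>
    compute_binned_means()
}

# Simulate one experiment and return its binned means (warnings from
# deliberately tiny or odd cohort sizes are incidental here).
sim_binned <- function(cohort_cfg, seed, label = "exp") {
  cfg <- pipeline_config(cohort = cohort_cfg, experiment_label = label)
  prep_trials(suppressWarnings(run_simulation(cfg, seed = seed)$trials))
}
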