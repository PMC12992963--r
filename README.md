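# priortime

Simulation and analysis of **multiple-prior acquisition in sensorimotor
interval timing**, for researchers studying Bayesian timing behavior in
coincidence (anticipated-onset) tasks.

## The problem and the model

When target intervals `T_S` are drawn from a prior distribution, reproduced
intervals regress toward the prior mean — more strongly for longer, noisier
intervals (scalar variability: sensory SD = `w·T_S` with Weber fraction
`w`). The mean response of a Bayesian observer with internal prior
N(μ, σ²) is

    T̄_R(T_S) = σ²/(σ² + w²T_S²) · T_S  +  w²T_S²/(σ² + w²T_S²) · μ

a convex combination of target and prior mean that crosses the unity line
exactly at `T_S = μ`. When *two* priors alternate trial by trial (short:
450–1050 ms; long: 1200–1800 ms, color-cued), the question is whether an
observer acquires two independent priors (two diverging curves) or one
generalized prior at their midpoint `M_priors = 1125` ms (one shared
curve). `priortime` implements the full pipeline around that question:

* **Design & simulation** — alternating, counterbalanced 640-trial
  schedules; synthetic cohorts of Bayesian observers with configurable
  prior merging per trial bin, motor noise, constant bias (undershoot),
  lapses and concomitant-response lags.
* **Preprocessing** — erroneous-trial exclusion, per-cell ±3 SD screening,
  binned means (two 320-trial bins), grand averages.
* **Curve fitting** — profile least squares of the one-prior and two-prior
  mean-response curves in the identified parametrization (μ, σ/w); fitted
  means and RSS are initial-value-independent by construction; implausible
  acquired means are flagged, with undershoot compensation and
  re-adjustment when needed.
* **Metrics & inference** — `T̄_R(M_priors)` and acquired-mean divergences
  `Δμ̂_prior`; a group-size-preserving permutation test for
  between-experiment divergence differences; AICc/Akaike-weight comparison
  of the one- vs two-prior models.

## Worked example

Simulate a control experiment (partially merged priors throughout) and a
test experiment in which a concomitant motor response sharpens prior
separation in the second half, then analyze and compare:

```r
library(priortime)

cfg_control <- pipeline_config(
  cohort = cohort_config(merge_lambda = c(0.6, 0.6)),
  experiment_label = "control", inference = list(n_perm = 2000))
cfg_cmr <- pipeline_config(
  design = design_config(cmr_prior = "short"),
  cohort = cohort_config(merge_lambda = c(0.6, 0.15)),
  experiment_label = "cmr", inference = list(n_perm = 2000))

out <- reproduce_study(cfg_control, cfg_cmr, seed = 42)
out$report
#> <timing_report>
#>   bin1: mu_hat short/long = 978.0/1269.7 ms (delta 291.6) | TR(1125) delta = 107.2 ms
#>       Akaike weights one/two: 0.000/1.000
#>       permutation p = 0.6935 (observed diff -20.5 ms)
#>   bin2: mu_hat short/long = 813.8/1450.9 ms (delta 637.1) | TR(1125) delta = 242.2 ms
#>       Akaike weights one/two: 0.000/1.000
#>       permutation p = 0 (observed diff 354.8 ms)
```

Reading the numbers: in trials 1–320 both cohorts are equally merged — the
acquired means sit well inside the true means (978/1270 vs 750/1500), and
the permutation test finds no divergence difference (p = 0.69). In trials
321–640 the test cohort's priors separate (acquired means 814/1451 ms,
divergence 637 ms; response curves 242 ms apart at 1125 ms), and the
observed test-minus-control divergence difference of 355 ms exceeds every
one of 2000 permutations (p = 0, Bonferroni-corrected threshold 0.025).

Lower-level entry points (`generate_schedule()`, `sample_cohort()`,
`simulate_experiment()`, `flag_invalid_trials()`, `remove_outliers()`,
`compute_binned_means()`, `grand_average()`, `fit_two_prior()`,
`fit_one_prior()`, `eval_metrics()`, `compensate_undershoot()`,
`compare_models()`, `permutation_test()`) compose the same pipeline piece
by piece; see the vignette `vignettes/prior-acquisition.Rmd` for the model,
conventions and design choices.

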