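# Statistical inference on the fitted curves: AICc / Akaike-weight model
# comparison (one generalized prior vs two independent priors) and a
# permutation test for between-experiment differences in the acquired-prior
# divergence.

#' Small-sample-corrected Akaike information criterion
#'
#' Gaussian-likelihood AICc from a residual sum of squares:
#' `n * log(rss / n) + 2 K + 2 K (K + 1) / (n - K - 1)`. By default the
#' residual variance counts as a fitted parameter (`K = k + 1`); set
#' `count_sigma = FALSE` for the `K = k` convention (the two differ only in
#' the constant-penalty terms and barely move the resulting weights at the
#' sample sizes involved here).
#'
#' @param rss Residual sum of squares.
#' @param n Number of residuals.
#' @param k Number of curve parameters (5 for the two-prior model, 3 for the
#'   one-prior model).
#' @param count_sigma Count the residual variance as a parameter?
#' @return AICc value (additive constants from the Gaussian density omitted,
#'   as usual when comparing models on the same data).
#' @export
compute_aicc <- function(rss, n, k, count_sigma = TRUE) {
  stopifnot(rss > 0, n >= 1, k >= 1)
  K <- k + as.integer(count_sigma)
  if (n <= K + 1) {
    stop(sprintf("AICc undefined: need n > K + 1 (n = %d, K = %d)", n, K),
         call. = FALSE)
  }
  n * log(rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' Normalized relative evidence `exp(-(AICc_i - min AICc) / 2)`, computed via
#' the min-shift for overflow safety; invariant to adding a constant to all
#' AICc values.
#'
#' @param aicc Numeric vector of (finite) AICc values.
#' @return Weights summing to 1, same order as `aicc`.
#' @examples
#' akaike_weights(c(0, 2)) # c(0.731, 0.269)
#' @export
akaike_weights <- function(aicc) {
  if (!all(is.finite(aicc))) stop("`aicc` must be finite", call. = FALSE)
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Compare the one-prior and two-prior models in one trial bin
#'
#' Fits both models to the grand-averaged mean responses of the given bin,
#' then scores them by AICc computed from the residuals of every
#' participant's binned means around each grand-average-fitted curve (n =
#' participants x grid points), and converts the AICc pair to Akaike weights.
#' A higher two-prior weight is evidence that two independent priors were
#' acquired.
#'
#' @param binned Output of [compute_binned_means()] (one experiment).
#' @param bin Trial bin to compare (1 or 2).
#' @param init_two,init_one Initial values for the fits.
#' @param count_sigma AICc parameter-count convention, see [compute_aicc()].
#' @param compensate If `TRUE`, subtract the bin's systematic bias (mean of
#'   grand-averaged response minus target) from grand-average and participant
#'   values before fitting and scoring.
#' @return A list of class `model_comparison`: `aicc_one`, `aicc_two`,
#'   `weight_one`, `weight_two`, `rss_one`, `rss_two`, `k_one`, `k_two`,
#'   `n_residuals`, plus the two fits.
#' @export
compare_models <- function(binned, bin = 1L,
                           init_two = default_init_two_prior(),
                           init_one = default_init_one_prior(),
                           count_sigma = TRUE, compensate = FALSE) {
  sub <- binned[binned$bin == bin, ]
  if (!nrow(sub)) stop("no rows for the requested bin", call. = FALSE)
  grand <- grand_average(sub)
  if (compensate) {
    comp <- compensate_undershoot(grand)
    grand <- comp$adjusted
    sub$t_r_mean <- sub$t_r_mean - comp$bias$bias[match(bin, comp$bias$bin)]
  }
  fit2 <- fit_two_prior(grand, init = init_two)
  fit1 <- fit_one_prior(grand, init = init_one)
  res2 <- sub$t_r_mean - predict(fit2, sub$t_s, sub$prior_label)
  res1 <- sub$t_r_mean - predict(fit1, sub$t_s)
  n <- nrow(sub)
  k_one <- 3L; k_two <- 5L
  aicc <- c(one = compute_aicc(sum(res1^2), n, k_one, count_sigma),
            two = compute_aicc(sum(res2^2), n, k_two, count_sigma))
  wts <- akaike_weights(aicc)
  structure(
    list(bin = bin, aicc_one = aicc[["one"]], aicc_two = aicc[["two"]],
         weight_one = wts[[1]], weight_two = wts[[2]],
         rss_one = sum(res1^2), rss_two = sum(res2^2),
         k_one = k_one, k_two = k_two, n_residuals = n,
         count_sigma = count_sigma, compensate = compensate,
         fit_one = fit1, fit_two = fit2),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model_comparison> bin %d | AICc one/two: %.1f/%.1f | Akaike weights one/two: %.3f/%.3f (n = %d)\n",
    x$bin, x$aicc_one, x$aicc_two, x$weight_one, x$weight_two, x$n_residuals))
  invisible(x)
}

# Cached profile fitter for a fixed t grid (hot path of the permutation
# loop): precomputes the grid-scan matrices so each call only touches the
# response vector.
.branch_fitter <- function(t, n_grid = 81L) {
  t2 <- t^2
  n <- length(t)
  lr_grid <- seq(.lr_bounds[1], .lr_bounds[2], length.out = n_grid)
  rho <- exp(lr_grid)
  A <- rho / (rho + matrix(t2, n_grid, n, byrow = TRUE))  # rho recycles by row
  B <- 1 - A
  AT <- A * matrix(t, n_grid, n, byrow = TRUE)
  sB2 <- rowSums(B * B)
  function(y) {
    Z <- matrix(y, n_grid, n, byrow = TRUE) - AT
    mu <- rowSums(B * Z) / sB2
    rss <- rowSums((Z - B * mu)^2)
    i <- which.min(rss)
    opt <- optimize(.branch_rss,
                    c(lr_grid[max(1L, i - 1L)], lr_grid[min(n_grid, i + 1L)]),
                    t2 = t2, t = t, y = y, tol = 1e-9)
    lr <- if (opt$objective <= rss[i]) opt$minimum else lr_grid[i]
    r2 <- exp(lr)
    a <- r2 / (r2 + t2)
    b <- 1 - a
    z <- y - a * t
    sum(b * z) / sum(b * b)
  }
}

# Participants x grid-point matrix of binned mean responses for one bin.
# Columns are ordered short prior first, then long, by t_s.
.profile_matrix <- function(binned, bin) {
  sub <- binned[binned$bin == bin, ]
  if (!nrow(sub)) stop("no rows for the requested bin", call. = FALSE)
  sub$prior_label <- factor(sub$prior_label, levels = c("short", "long"))
  sub <- sub[order(sub$prior_label, sub$t_s), ]
  wide <- tidyr::pivot_wider(
    sub[, c("participant_id", "prior_label", "t_s", "t_r_mean")],
    names_from = c("prior_label", "t_s"), values_from = "t_r_mean")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant_id
  if (anyNA(m)) stop("incomplete mean-response profiles in this bin", call. = FALSE)
  key <- unique(sub[, c("prior_label", "t_s")])
  attr(m, "prior_label") <- as.character(key$prior_label)
  attr(m, "t_s") <- key$t_s
  m
}

#' Permutation test of the between-experiment difference in prior divergence
#'
#' Tests whether the acquired-prior divergence (`delta mu_hat`: long- minus
#' short-prior acquired mean read from a grand-average two-prior fit) is
#' larger in a test experiment than in a control experiment, for one trial
#' bin. Participants' mean-response profiles are pooled across the two
#' experiments and randomly reassigned to the two labels (preserving group
#' sizes); each permutation's relabeled groups are grand-averaged and
#' refitted, and the difference in divergence (test minus control) is
#' recomputed. The p-value is the fraction of permutation differences
#' strictly exceeding the observed difference (`n_exceed / n_perm`
#' convention, which admits p = 0). Permutations yielding an irregular
#' acquired mean are removed from the denominator by default; a
#' Bonferroni-corrected threshold `alpha / n_comparisons` is reported
#' alongside.
#'
#' @param binned_control,binned_test [compute_binned_means()] output for the
#'   control and test experiments; equal participant counts and identical
#'   target-interval grids required.
#' @param bin Trial bin to test (bins are permuted independently).
#' @param n_perm Number of permutations (10000 in the canonical analysis).
#' @param seed Integer seed for the reassignments.
#' @param compensate `"none"`, or `"subtract"` to remove each (permuted)
#'   group's systematic bias -- mean of grand-averaged response minus target --
#'   before every fit, as appropriate when the test experiment shows a
#'   systematic undershoot.
#' @param irregular_criterion `"magnitude"` flags `|mu_hat| >
#'   magnitude_limit`; `"range"` flags values outside `support_range`.
#' @param magnitude_limit,support_range Irregularity thresholds (ms).
#' @param drop_irregular Remove irregular permutations from numerator and
#'   denominator (default); if `FALSE` they are kept.
#' @param alpha,n_comparisons Nominal level and Bonferroni divisor (two trial
#'   bins by default).
#' @return A list of class `permutation_result`: `observed_diff`, `n_perm`,
#'   `n_exceed`, `n_removed_irregular`, `p_value`, `alpha_corrected`, `seed`,
#'   `samples` (the retained permutation differences).
#' @export
permutation_test <- function(binned_control, binned_test, bin = 2L,
                             n_perm = 10000L, seed = 1L,
                             compensate = c("none", "subtract"),
                             irregular_criterion = c("magnitude", "range"),
                             magnitude_limit = 10000,
                             support_range = c(450, 1800),
                             drop_irregular = TRUE,
                             alpha = 0.05, n_comparisons = 2L) {
  compensate <- match.arg(compensate)
  irregular_criterion <- match.arg(irregular_criterion)
  mc <- .profile_matrix(binned_control, bin)
  mt <- .profile_matrix(binned_test, bin)
  if (!identical(attr(mc, "t_s"), attr(mt, "t_s")) ||
      !identical(attr(mc, "prior_label"), attr(mt, "prior_label"))) {
    stop("control and test experiments use different (prior, t_s) grids",
         call. = FALSE)
  }
  if (nrow(mc) != nrow(mt)) {
    stop("control and test experiments must have equal participant counts",
         call. = FALSE)
  }
  t_grid <- attr(mc, "t_s")
  is_short <- attr(mc, "prior_label") == "short"
  fit_short <- .branch_fitter(t_grid[is_short])
  fit_long <- .branch_fitter(t_grid[!is_short])

  delta_and_mus <- function(gm) {
    if (compensate == "subtract") gm <- gm - mean(gm - t_grid)
    c(fit_short(gm[is_short]), fit_long(gm[!is_short]))
  }
  is_irregular <- function(mus) {
    if (irregular_criterion == "magnitude") any(abs(mus) > magnitude_limit)
    else any(mus < support_range[1] | mus > support_range[2])
  }

  mus_c <- delta_and_mus(colMeans(mc))
  mus_t <- delta_and_mus(colMeans(mt))
  observed <- (mus_t[2] - mus_t[1]) - (mus_c[2] - mus_c[1])
  if (is_irregular(c(mus_c, mus_t))) {
    warning("irregular acquired mean in the observed (unpermuted) fits")
  }

  pooled <- rbind(mt, mc)
  n_g <- nrow(mt)
  set.seed(seed)
  diffs <- numeric(n_perm)
  irr <- logical(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(2L * n_g, n_g)
    m_t <- delta_and_mus(colMeans(pooled[idx, , drop = FALSE]))
    m_c <- delta_and_mus(colMeans(pooled[-idx, , drop = FALSE]))
    diffs[i] <- (m_t[2] - m_t[1]) - (m_c[2] - m_c[1])
    irr[i] <- is_irregular(c(m_t, m_c))
  }
  n_removed <- if (drop_irregular) sum(irr) else 0L
  if (n_removed > 0.1 * n_perm) {
    warning(sprintf("%.1f%% of permutations removed as irregular",
                    100 * n_removed / n_perm))
  }
  kept <- if (drop_irregular) diffs[!irr] else diffs
  n_exceed <- sum(kept > observed)
  structure(
    list(observed_diff = observed, bin = bin, n_perm = n_perm,
         n_exceed = n_exceed, n_removed_irregular = n_removed,
         p_value = n_exceed / (n_perm - n_removed),
         alpha_corrected = alpha / n_comparisons, seed = seed,
         compensate = compensate, samples = kept),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> bin %d | observed diff = %.1f ms | p = %.4g (%d/%d%s) | alpha_corr = %.3g\n",
    x$bin, x$observed_diff, x$p_value, x$n_exceed,
    x$n_perm - x$n_removed_irregular,
    if (x$n_removed_irregular) sprintf(", %d irregular removed",
                                       x$n_removed_irregular) else "",
    x$alpha_corrected))
  invisible(x)
}
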