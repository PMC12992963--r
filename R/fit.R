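# Least-squares fitting of the mean-response curves.
#
# A single mean-response curve identifies only the prior mean mu and the
# ratio r = sigma / w (the curve is invariant under (sigma, w) -> (c sigma,
# c w)).  Each branch is therefore fitted in the identified parametrization
# (mu, rho = r^2), where for fixed rho the least-squares mu has a closed
# form; the residual sum of squares is profiled over log(rho) by a coarse
# grid scan followed by stats::optimize() refinement.  This makes the fitted
# mu, curve values and RSS independent of initial values by construction.
# The initial values are still used to back-compute nominal (non-identified)
# sigma and w for reporting: sigma_reported = r_fitted * w_init.

.lr_bounds <- log(c(1e-2, 1e13))

# Profile least squares for one branch: for each rho, the optimal mu is the
# weighted regression of (y - a t) on (1 - a), a = rho / (rho + t^2).
.branch_rss <- function(lr, t2, t, y) {
  rho <- exp(lr)
  a <- rho / (rho + t2)
  b <- 1 - a
  z <- y - a * t
  mu <- sum(b * z) / sum(b * b)
  sum((z - b * mu)^2)
}

.fit_branch <- function(t, y, n_grid = 81L) {
  stopifnot(length(t) == length(y), length(unique(t)) >= 2L)
  t2 <- t^2
  lr_grid <- seq(.lr_bounds[1], .lr_bounds[2], length.out = n_grid)
  rss_grid <- vapply(lr_grid, .branch_rss, numeric(1), t2 = t2, t = t, y = y)
  i <- which.min(rss_grid)
  lo <- lr_grid[max(1L, i - 1L)]
  hi <- lr_grid[min(n_grid, i + 1L)]
  opt <- optimize(.branch_rss, c(lo, hi), t2 = t2, t = t, y = y, tol = 1e-9)
  lr <- if (opt$objective <= rss_grid[i]) opt$minimum else lr_grid[i]
  rho <- exp(lr)
  a <- rho / (rho + t2)
  b <- 1 - a
  z <- y - a * t
  mu <- sum(b * z) / sum(b * b)
  list(mu = mu, rho = rho, rss = sum((z - b * mu)^2), converged = TRUE)
}

.check_points <- function(points, need_prior = TRUE) {
  cols <- c(if (need_prior) "prior_label", "t_s", "t_r_mean")
  missing <- setdiff(cols, names(points))
  if (length(missing)) {
    stop(sprintf("`points` is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (all(abs(points$t_r_mean - points$t_s) < 1e-8)) {
    stop(errorCondition(
      "points lie exactly on the unity line: the curve parameters are not identifiable",
      class = c("priortime_unidentifiable", "error", "condition")))
  }
  invisible(points)
}

#' Construct a two-prior curve fit object
#'
#' Low-level constructor, mainly for composing results programmatically; use
#' [fit_two_prior()] to fit data. `sigma_short`, `sigma_long` and `w` are not
#' individually identified by a mean-response curve; only `mu_*` and the
#' ratios `sigma_* / w` are.
#'
#' @param mu_short,mu_long Prior means (ms).
#' @param sigma_short,sigma_long Prior SDs (ms).
#' @param w Weber fraction (> 0).
#' @param rss Residual sum of squares (ms^2).
#' @param n_points Number of fitted points.
#' @param converged Logical optimizer status.
#' @param init Initial values used (list), if any.
#' @return Object of class `two_prior_fit`.
#' @export
two_prior_fit <- function(mu_short, mu_long, sigma_short, sigma_long, w,
                          rss = NA_real_, n_points = NA_integer_,
                          converged = TRUE, init = NULL) {
  stopifnot(w > 0, sigma_short > 0, sigma_long > 0)
  structure(
    list(mu_short = mu_short, mu_long = mu_long,
         sigma_short = sigma_short, sigma_long = sigma_long, w = w,
         r_short = sigma_short / w, r_long = sigma_long / w,
         rss = rss, n_points = n_points, converged = converged, init = init),
    class = "two_prior_fit"
  )
}

#' Construct a one-prior (generalized) curve fit object
#'
#' @param mu_wide Generalized prior mean (ms).
#' @param sigma_wide Generalized prior SD (ms).
#' @inheritParams two_prior_fit
#' @return Object of class `one_prior_fit`.
#' @export
one_prior_fit <- function(mu_wide, sigma_wide, w,
                          rss = NA_real_, n_points = NA_integer_,
                          converged = TRUE, init = NULL) {
  stopifnot(w > 0, sigma_wide > 0)
  structure(
    list(mu_wide = mu_wide, sigma_wide = sigma_wide, w = w,
         r_wide = sigma_wide / w,
         rss = rss, n_points = n_points, converged = converged, init = init),
    class = "one_prior_fit"
  )
}

#' Default initial values for the curve fits
#'
#' The two-prior initial values are the true parameters of the default design
#' (means 750 and 1500 ms, SDs 237 ms) with Weber fraction 0.15; the
#' one-prior initial values are the pooled-support moments (1125, 454 ms)
#' with the same Weber fraction. The fitted prior means, curve values and RSS
#' do not depend on these; the reported nominal `sigma`/`w` decomposition
#' does (see [fit_two_prior()]).
#'
#' @name fit_inits
#' @return Named lists of initial values.
#' @export
default_init_two_prior <- function() {
  list(mu_short = 750, mu_long = 1500, sigma_short = 237, sigma_long = 237,
       w = 0.15)
}

#' @rdname fit_inits
#' @export
default_init_one_prior <- function() {
  list(mu_wide = 1125, sigma_wide = 454, w = 0.15)
}

#' Fit the two-prior mean-response model
#'
#' Unconstrained least squares of the two-branch curve (short-prior branch
#' over its target range, long-prior branch over its) against mean responses.
#' Because the two branches share no identified parameter (the nominal Weber
#' fraction is shared but only the per-branch ratios `sigma/w` are
#' identified), each branch is fitted by profile least squares in
#' `(mu, sigma/w)`. Fitted prior means are not constrained to the stimulus
#' range: implausible ("irregular") values are possible and are flagged
#' downstream by [eval_metrics()], never clipped.
#'
#' @param points Data frame with columns `prior_label` (`"short"`/`"long"`),
#'   `t_s` and `t_r_mean` (one bin's grand-average or per-participant
#'   profile). At least two distinct `t_s` per branch.
#' @param init Initial values (see [default_init_two_prior()]); used only for
#'   the nominal `sigma`/`w` report.
#' @return A [two_prior_fit()] object. `rss` is the sum over both branches.
#' @examples
#' pts <- data.frame(
#'   prior_label = rep(c("short", "long"), each = 5),
#'   t_s = c(seq(450, 1050, 150), seq(1200, 1800, 150)))
#' pts$t_r_mean <- predict_mean_response(
#'   pts$t_s, mu = ifelse(pts$prior_label == "short", 750, 1500),
#'   sigma = 237, w = 0.15)
#' fit_two_prior(pts)
#' @export
fit_two_prior <- function(points, init = default_init_two_prior()) {
  .check_points(points)
  fits <- lapply(c("short", "long"), function(p) {
    sub <- points[points$prior_label == p, ]
    if (dplyr::n_distinct(sub$t_s) < 2L) {
      stop(sprintf("need at least 2 distinct t_s values for the %s prior", p),
           call. = FALSE)
    }
    .fit_branch(sub$t_s, sub$t_r_mean)
  })
  w <- init$w
  two_prior_fit(
    mu_short = fits[[1]]$mu, mu_long = fits[[2]]$mu,
    sigma_short = sqrt(fits[[1]]$rho) * w,
    sigma_long = sqrt(fits[[2]]$rho) * w,
    w = w,
    rss = fits[[1]]$rss + fits[[2]]$rss,
    n_points = nrow(points),
    converged = fits[[1]]$converged && fits[[2]]$converged,
    init = init
  )
}

#' Fit the one-prior (generalized) mean-response model
#'
#' Single curve over the full target range; nested within the two-prior model
#' (equal branch parameters), so its RSS can never fall below the two-prior
#' fit's on the same points.
#'
#' @param points Data frame with columns `t_s` and `t_r_mean` covering the
#'   full target range (a `prior_label` column, if present, is ignored).
#' @param init Initial values (see [default_init_one_prior()]).
#' @return A [one_prior_fit()] object.
#' @export
fit_one_prior <- function(points, init = default_init_one_prior()) {
  .check_points(points, need_prior = FALSE)
  if (dplyr::n_distinct(points$t_s) < 2L) {
    stop("need at least 2 distinct t_s values", call. = FALSE)
  }
  fit <- .fit_branch(points$t_s, points$t_r_mean)
  one_prior_fit(
    mu_wide = fit$mu,
    sigma_wide = sqrt(fit$rho) * init$w,
    w = init$w,
    rss = fit$rss, n_points = nrow(points),
    converged = fit$converged, init = init
  )
}

#' @export
predict.two_prior_fit <- function(object, t_s, prior_label, ...) {
  stopifnot(length(t_s) == length(prior_label) || length(prior_label) == 1L)
  rho <- ifelse(prior_label == "short", object$r_short^2, object$r_long^2)
  mu <- ifelse(prior_label == "short", object$mu_short, object$mu_long)
  .curve_value(t_s, mu, rho)
}

#' @export
predict.one_prior_fit <- function(object, t_s, ...) {
  .curve_value(t_s, object$mu_wide, object$r_wide^2)
}

#' @export
print.two_prior_fit <- function(x, ...) {
  cat(sprintf(
    "<two_prior_fit> mu_short = %.1f, mu_long = %.1f ms | sigma/w ratios: %.1f, %.1f ms\n",
    x$mu_short, x$mu_long, x$r_short, x$r_long))
  cat(sprintf("  rss = %.3f ms^2 on %s points (nominal sigma, w not identified)\n",
              x$rss, x$n_points))
  invisible(x)
}

#' @export
print.one_prior_fit <- function(x, ...) {
  cat(sprintf("<one_prior_fit> mu_wide = %.1f ms | sigma/w ratio: %.1f ms | rss = %.3f ms^2\n",
              x$mu_wide, x$r_wide, x$rss))
  invisible(x)
}
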