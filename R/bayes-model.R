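# Bayesian observer model for interval timing with scalar variability.
#
# An observer senses a target interval T_S with Weber-scaled noise
# (sigma_sensed = w * T_S) and combines the measurement with a Gaussian
# internal prior N(mu, sigma^2).  The across-trial mean reproduction is a
# precision-weighted convex combination of T_S and mu; only mu and the
# ratio sigma/w are identified by a single mean-response curve.

#' Construct a discrete prior specification
#'
#' A prior is a discrete set of target intervals (ms) from which stimuli are
#' drawn. Its mean and SD (sample convention, n - 1 denominator) are the
#' "true" parameters used as fitting initial values; for the canonical short
#' prior \{450, 600, ..., 1050\} these are 750 and 237 ms, and for the pooled
#' ten-value support 1125 and 454 ms.
#'
#' @param label Prior label, e.g. `"short"`, `"long"` or `"wide"`.
#' @param support Strictly increasing vector of positive intervals (ms),
#'   at least two values.
#' @return An object of class `prior_spec` with fields `label`, `support`,
#'   `mu_prior` and `sigma_prior`.
#' @examples
#' prior_spec("short", seq(450, 1050, by = 150))
#' @export
prior_spec <- function(label, support) {
  stopifnot(is.character(label), length(label) == 1L)
  support <- as.numeric(support)
  if (length(support) < 2L) {
    stop("`support` needs at least two values (SD undefined otherwise)",
         call. = FALSE)
  }
  if (anyNA(support) || any(support <= 0)) {
    stop("`support` values must be positive and non-missing", call. = FALSE)
  }
  if (is.unsorted(support, strictly = TRUE)) {
    stop("`support` must be strictly increasing", call. = FALSE)
  }
  m <- prior_moments(support)
  structure(
    list(label = label, support = support,
         mu_prior = m[["mu"]], sigma_prior = m[["sigma"]]),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec '%s'> support: %s ms | mu = %.1f ms, sigma = %.1f ms\n",
              x$label, paste(x$support, collapse = ", "),
              x$mu_prior, x$sigma_prior))
  invisible(x)
}

#' The two canonical priors of the alternating-prior timing design
#'
#' Short prior: 450--1050 ms in 150 ms steps; long prior: 1200--1800 ms.
#'
#' @return Named list with `prior_spec` elements `short` and `long`.
#' @export
default_priors <- function() {
  list(short = prior_spec("short", seq(450, 1050, by = 150)),
       long  = prior_spec("long",  seq(1200, 1800, by = 150)))
}

#' Mean and SD of a discrete prior support
#'
#' @param support Numeric vector of at least two distinct interval values (ms).
#' @return Named numeric vector `c(mu, sigma)`; `sigma` uses the n - 1
#'   denominator.
#' @export
prior_moments <- function(support) {
  support <- as.numeric(support)
  if (length(unique(support)) < 2L) {
    stop("need at least two distinct support values", call. = FALSE)
  }
  c(mu = mean(support), sigma = sd(support))
}

#' Midpoint of two prior means (the generalized-prior mean)
#'
#' @param priors List of two `prior_spec` objects.
#' @return The mean of the two prior means (1125 ms for the default design).
#' @export
m_priors <- function(priors = default_priors()) {
  stopifnot(length(priors) == 2L)
  mean(vapply(priors, function(p) p$mu_prior, numeric(1)))
}

#' Weber-scaled sensory standard deviation
#'
#' Scalar variability: the SD of the sensed interval grows linearly with the
#' target interval, `sigma_sensed = w * t_s`.
#'
#' @param t_s Target interval(s), ms, positive.
#' @param w Weber fraction, dimensionless, non-negative.
#' @return `w * t_s` (ms).
#' @export
sensory_sd <- function(t_s, w) {
  if (any(t_s <= 0)) stop("`t_s` must be positive", call. = FALSE)
  if (any(w < 0)) stop("`w` must be non-negative", call. = FALSE)
  w * t_s
}

#' Predicted mean reproduced interval
#'
#' The across-trial mean response at target interval `t_s` for an observer
#' with internal prior N(`mu`, `sigma`^2) and Weber fraction `w`:
#' \deqn{\bar T_R = \frac{\sigma^2}{\sigma^2 + w^2 T_S^2} T_S +
#'       \frac{w^2 T_S^2}{\sigma^2 + w^2 T_S^2} \mu}
#' a convex combination of the target and the prior mean whose weight on the
#' prior grows with `t_s` (stronger central tendency for longer, noisier
#' intervals).  The curve depends on `sigma` and `w` only through the ratio
#' `sigma / w`.
#'
#' @param t_s Target interval(s), ms, positive.
#' @param mu Prior mean, ms.
#' @param sigma Prior SD, ms, positive.
#' @param w Weber fraction, non-negative. `w = 0` gives the identity
#'   (no shrinkage).
#' @return Predicted mean response(s), ms.
#' @examples
#' predict_mean_response(1050, mu = 750, sigma = 237, w = 0.15) # ~958 ms
#' @export
predict_mean_response <- function(t_s, mu, sigma, w) {
  if (any(t_s <= 0)) stop("`t_s` must be positive", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (w < 0) stop("`w` must be non-negative", call. = FALSE)
  if (w == 0) return(t_s + 0 * mu)
  .curve_value(t_s, mu, (sigma / w)^2)
}

# Identified form of the mean-response curve: rho = (sigma / w)^2.
.curve_value <- function(t_s, mu, rho) {
  a <- rho / (rho + t_s^2)
  a * t_s + (1 - a) * mu
}

#' Intersection of the mean-response curve with the unity line
#'
#' The unique target interval at which the predicted mean response equals the
#' target. Algebraically this is the prior mean `mu`: the prior-weight in the
#' convex combination is nonzero for `w > 0`, forcing `t_s = mu` at the fixed
#' point. This identity is what lets an acquired prior mean be read off a
#' fitted curve.
#'
#' @inheritParams predict_mean_response
#' @return `mu` (ms); for `w = 0` the whole curve lies on the unity line, so
#'   `NA_real_` is returned with a `priortime_degenerate_curve` warning.
#' @export
unity_intersection <- function(mu, sigma, w) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (w < 0) stop("`w` must be non-negative", call. = FALSE)
  if (w == 0) {
    warning(warningCondition(
      "w = 0: the curve coincides with the unity line; intersection undefined",
      class = "priortime_degenerate_curve"))
    return(NA_real_)
  }
  mu
}
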