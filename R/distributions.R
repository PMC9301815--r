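#' Distribution specifications for probabilistic sensitivity analysis
#'
#' Constructors that fit sampling distributions from the published summary
#' form of each parameter: a point estimate with a 95\% CI, exact event
#' counts, or a mean with a standard error. Each returns a
#' `txace_dist` object holding the family and natural parameters; draw from
#' it with [rdist()].
#'
#' @name distributions
NULL

.new_dist <- function(family, pars, mean, median = NULL) {
  structure(list(family = family, pars = pars, mean = mean,
                 median = if (is.null(median)) mean else median),
            class = "txace_dist")
}

#' @describeIn distributions Log-normal from a point estimate (treated as the
#'   log-scale median) and a 95\% CI: `meanlog = log(point)`,
#'   `sdlog = (log(hi) - log(lo)) / (2 * 1.96)`. Used for risk ratios and
#'   standardised mortality ratios, whose CIs are symmetric on the log scale.
#' @param point,lo,hi Point estimate and 95\% CI bounds.
#' @export
#' @examples
#' lognormal_from_ci(1.03, 0.92, 1.16)$pars
lognormal_from_ci <- function(point, lo, hi) {
  if (lo <= 0 || point <= 0) stop("log-normal requires positive point and bounds")
  if (!(lo <= point && point <= hi)) stop("CI must bracket the point estimate")
  sdlog <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  .new_dist("lognormal", list(meanlog = log(point), sdlog = sdlog),
            mean = exp(log(point) + sdlog^2 / 2), median = point)
}

#' @describeIn distributions Beta from exact event counts: shape parameters
#'   `(k, n - k)`, mean `k / n`. Degenerate counts (k = 0 or k = n) give a
#'   point mass.
#' @param k,n Event count and denominator.
#' @export
beta_from_counts <- function(k, n) {
  if (n <= 0) stop("denominator must be positive")
  if (k < 0 || k > n) stop("event count must lie in [0, n]")
  if (k == 0 || k == n) {
    return(.new_dist("fixed", list(value = k / n), mean = k / n))
  }
  .new_dist("beta", list(shape1 = k, shape2 = n - k), mean = k / n)
}

#' @describeIn distributions Beta from a mean and 95\% CI by method of
#'   moments, with SE = (hi - lo) / (2 * 1.96). Used for the survivor
#'   utility. Errors if the implied variance is infeasible for a beta.
#' @param mean_ Mean in (0, 1).
#' @export
beta_from_ci <- function(mean_, lo, hi) {
  if (!(mean_ > 0 && mean_ < 1)) stop("mean must lie in (0, 1)")
  if (!(lo <= mean_ && mean_ <= hi)) stop("CI must bracket the mean")
  se <- (hi - lo) / (2 * stats::qnorm(0.975))
  if (se == 0) return(.new_dist("fixed", list(value = mean_), mean = mean_))
  v <- se^2
  if (v >= mean_ * (1 - mean_)) stop("variance infeasible for a beta distribution")
  nu <- mean_ * (1 - mean_) / v - 1
  .new_dist("beta", list(shape1 = mean_ * nu, shape2 = (1 - mean_) * nu),
            mean = mean_)
}

#' @describeIn distributions Gamma from a mean and standard error:
#'   `shape = (mean / se)^2`, `scale = se^2 / mean`. Used for lengths of
#'   stay, transfusion units and post-discharge costs. A zero SE (or a zero
#'   mean) gives a point mass: zero-mean resource items are held fixed, not
#'   sampled.
#' @param se Standard error, >= 0.
#' @export
gamma_from_mean_se <- function(mean_, se) {
  if (mean_ < 0 || se < 0) stop("mean and SE must be non-negative")
  if (se == 0 || mean_ == 0) {
    return(.new_dist("fixed", list(value = mean_), mean = mean_))
  }
  .new_dist("gamma", list(shape = (mean_ / se)^2, scale = se^2 / mean_),
            mean = mean_)
}

#' @describeIn distributions A point mass (parameter excluded from the PSA).
#' @param value The fixed value.
#' @export
fixed_dist <- function(value) .new_dist("fixed", list(value = value), mean = value)

#' Draw from a fitted distribution specification
#'
#' @param spec A `txace_dist`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
rdist <- function(spec, n = 1) {
  p <- spec$pars
  switch(spec$family,
         fixed = rep(p$value, n),
         lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
         beta = stats::rbeta(n, p$shape1, p$shape2),
         gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
         stop("unknown distribution family: ", spec$family))
}
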