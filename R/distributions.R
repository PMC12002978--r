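# Samplers for the three distribution families used by the model:
# range-clipped normal, BetaPERT, and lognormal parameterized by its
# arithmetic moments. All draw from R's global RNG stream, so a call to
# set.seed() fully determines every sequence.

#' Draw from a normal distribution clipped to a range by resampling
#'
#' Draws from `Normal(mean, sd)` and resamples any value falling outside
#' `[lower, upper]` until all draws lie inside the range. Resampling (rather
#' than truncating values at the bound) avoids piling probability mass at the
#' edges; for the model's default parameters, with coefficients of variation
#' near 10% and bounds two or more standard deviations away, the clipped mass
#' is negligible and the sample mean is indistinguishable from `mean`.
#'
#' @param n Number of draws.
#' @param mean Mean of the unclipped normal.
#' @param sd Standard deviation, `>= 0`. `sd = 0` returns `mean` exactly.
#' @param lower,upper Clipping range (defaults: unbounded).
#' @param max_tries Resampling rounds allowed before failing; a table whose
#'   bounds exclude essentially all normal mass errors out rather than
#'   looping forever.
#' @return Numeric vector of length `n`, all values in `[lower, upper]`.
#' @examples
#' set.seed(1)
#' x <- sample_normal(1000, 0.077, 0.007, lower = 0, upper = 1)
#' range(x)
#' @export
sample_normal <- function(n, mean, sd, lower = -Inf, upper = Inf,
                          max_tries = 1000L) {
  if (sd < 0) stop("`sd` must be >= 0, got ", sd)
  if (lower >= upper) stop("`lower` must be < `upper`")
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("clipped-normal resampling failed to land in [", lower, ", ",
           upper, "] after ", max_tries, " rounds (mean = ", mean,
           ", sd = ", sd, ")")
    }
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

check_pert_args <- function(min, mode, max) {
  if (!(min <= mode && mode <= max)) {
    stop("BetaPERT requires min <= mode <= max, got (", min, ", ", mode,
         ", ", max, ")")
  }
  if (!(min < max)) stop("BetaPERT requires min < max, got min = max = ", min)
  invisible(TRUE)
}

#' Mean of a BetaPERT distribution
#'
#' The classical PERT three-point estimate with shape constant `lambda = 4`:
#' `(min + 4 * mode + max) / 6`.
#'
#' @param min,mode,max Minimum, most-likely, and maximum values, with
#'   `min <= mode <= max` and `min < max`.
#' @return The distribution mean.
#' @examples
#' betapert_mean(0.69, 0.75, 1.83) # 0.92
#' @export
betapert_mean <- function(min, mode, max) {
  check_pert_args(min, mode, max)
  (min + 4 * mode + max) / 6
}

#' Draw from a BetaPERT distribution
#'
#' Samples `min + (max - min) * B` with `B ~ Beta(alpha, beta)`,
#' `alpha = 1 + 4 * (mode - min) / (max - min)` and
#' `beta = 1 + 4 * (max - mode) / (max - min)` (the classical PERT with
#' `lambda = 4`). Every draw lies in `[min, max]`.
#'
#' @inheritParams betapert_mean
#' @param n Number of draws.
#' @return Numeric vector of length `n` in `[min, max]`.
#' @export
sample_betapert <- function(n, min, mode, max) {
  check_pert_args(min, mode, max)
  span <- max - min
  alpha <- 1 + 4 * (mode - min) / span
  beta <- 1 + 4 * (max - mode) / span
  min + span * stats::rbeta(n, alpha, beta)
}

#' Lognormal hyperparameters matching arithmetic moments
#'
#' Returns `(mu, sigma)` of the underlying normal such that the lognormal's
#' arithmetic mean and standard deviation equal the inputs:
#' `sigma^2 = log(1 + sd^2 / mean^2)`, `mu = log(mean) - sigma^2 / 2`.
#' With `sd = 0` this degenerates to `(log(mean), 0)`.
#'
#' @param mean Arithmetic mean, `> 0`.
#' @param sd Arithmetic standard deviation, `>= 0`.
#' @return A list with elements `mu` and `sigma`.
#' @examples
#' lognormal_params_from_moments(59, 29.5)
#' @export
lognormal_params_from_moments <- function(mean, sd) {
  if (mean <= 0) stop("lognormal `mean` must be > 0, got ", mean)
  if (sd < 0) stop("`sd` must be >= 0, got ", sd)
  sigma2 <- log1p((sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Draw from a lognormal distribution specified by arithmetic moments
#'
#' @inheritParams lognormal_params_from_moments
#' @param n Number of draws.
#' @return Numeric vector of length `n`, strictly positive; its empirical
#'   mean and SD converge to `mean` and `sd` as `n` grows.
#' @export
sample_lognormal_from_moments <- function(n, mean, sd) {
  if (sd == 0) {
    if (mean <= 0) stop("lognormal `mean` must be > 0, got ", mean)
    return(rep(mean, n))
  }
  p <- lognormal_params_from_moments(mean, sd)
  stats::rlnorm(n, meanlog = p$mu, sdlog = p$sigma)
}
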