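# Closed-form MSE comparisons and minimum-sample-size thresholds.
#
# MSE here is the expected summed squared error across the p condition
# means, E[sum_i (muhat_i - mu_i)^2], which decomposes into total
# variance plus total squared bias.  All expressions are distribution
# free: they require only a common within-condition variance sigma^2.

needs_env <- function(env, fields) {
  stopifnot(inherits(env, "design_env"))
  missing <- fields[vapply(fields, function(f) is.null(env[[f]]), logical(1))]
  if (length(missing))
    stop("incomplete environment: needs ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Closed-form MSE of the vector of sample means
#'
#' Sample means are unbiased, so their MSE is pure variance:
#' \eqn{p\sigma^2/n}.
#'
#' @param env a \code{\link{design_environment}} with \code{p}, \code{n},
#'   \code{sigma}.
#' @return Scalar MSE in squared DV units.
#' @examples
#' mse_sample_means(design_environment(4, 10, 100, f2 = 0.05))  # 4000
#' @export
mse_sample_means <- function(env) {
  needs_env(env, c("p", "n", "sigma"))
  env$p * env$sigma^2 / env$n
}

#' Closed-form MSE of the zero estimator
#'
#' The grand mean has variance \eqn{\sigma^2/(pn)}; summed over the p
#' identical entries the total variance is \eqn{\sigma^2/n}, and the
#' squared bias is \eqn{\sum_i(\mu_i-\mu^*)^2 = p f^2 \sigma^2}, giving
#' \deqn{MSE_z = \sigma^2/n + p f^2 \sigma^2.}
#'
#' @inheritParams mse_sample_means
#' @return Scalar MSE in squared DV units.
#' @export
mse_zero <- function(env) {
  needs_env(env, c("p", "n", "sigma", "f2"))
  env$sigma^2 / env$n + env$p * env$f2 * env$sigma^2
}

#' Closed-form MSE of the shrinkage-scaled random estimator
#'
#' The random estimator trades squared bias
#' \deqn{(p-1) f^2 \sigma^2}
#' for a reduction in total variance
#' \deqn{\frac{\sigma^2\left(p + (p-1)(p-\sqrt{p^2-p})^2\right)}{p\,n}
#'       + (p-1)\left(2p-1-2\sqrt{p^2-p}\right) f^2 \sigma^2.}
#' The two pieces sum exactly to the sample-mean MSE \eqn{p\sigma^2/n}
#' at the continuous threshold \eqn{n = \sqrt{p(p-1)}/(p f^2)}
#' (see \code{\link{min_n_random}}).
#'
#' @inheritParams mse_sample_means
#' @return A list with components \code{bias_sq}, \code{variance} and
#'   \code{total}, all in squared DV units.
#' @examples
#' mse_random(design_environment(4, 10, 100, f2 = 0.05))$total  # ~2823.1
#' @export
mse_random <- function(env) {
  needs_env(env, c("p", "n", "sigma", "f2"))
  p <- env$p; s2 <- env$sigma^2; f2 <- env$f2
  root <- sqrt(p^2 - p)                  # reused so the boundary is exact
  bias_sq <- (p - 1) * f2 * s2
  variance <- s2 * (p + (p - 1) * (p - root)^2) / (p * env$n) +
    (p - 1) * (2 * p - 1 - 2 * root) * f2 * s2
  list(bias_sq = bias_sq, variance = variance, total = bias_sq + variance)
}

min_n_result <- function(threshold) {
  if (!is.finite(threshold))
    return(list(threshold = Inf, min_n = Inf))
  # an exact tie at an integer boundary already counts as acceptable
  list(threshold = threshold, min_n = as.integer(ceiling(threshold)))
}

#' Minimum n for sample means to beat the random estimator
#'
#' The random estimator has smaller MSE than sample means exactly when
#' \eqn{n < \sqrt{p(p-1)}/(p f^2)}.  The returned \code{min_n} is the
#' smallest integer sample size per condition at which sample means are
#' at least as accurate (ties at the exact boundary count as acceptable).
#' At \eqn{f^2 = 0} sample means are never preferable; both components
#' are returned as \code{Inf} rather than raising an error, so planning
#' tables render cleanly.
#'
#' @param p number of conditions (at least 2).
#' @param f2 nonnegative effect size.
#' @return List with \code{threshold} (continuous bound, observations per
#'   condition) and \code{min_n} (integer).
#' @examples
#' min_n_random(5, 0.05)  # threshold 17.9, min_n 18
#' @export
min_n_random <- function(p, f2) {
  if (!is.numeric(p) || length(p) != 1L || p != round(p) || p < 2)
    stop("`p` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(f2) || length(f2) != 1L || is.na(f2) || f2 < 0)
    stop("`f2` must be a single nonnegative number", call. = FALSE)
  min_n_result(if (f2 == 0) Inf else sqrt(p * (p - 1)) / (p * f2))
}

#' Minimum n for sample means to beat the zero estimator
#'
#' The zero estimator has smaller MSE than sample means exactly when
#' \eqn{n < (p-1)/(p f^2)}.  The random-estimator threshold exceeds this
#' one by the factor \eqn{\sqrt{p/(p-1)}} at every \eqn{(p, f^2)}.
#'
#' @inheritParams min_n_random
#' @return List with \code{threshold} and \code{min_n}.
#' @examples
#' min_n_zero(5, 0.05)  # threshold 16, min_n 16
#' @export
min_n_zero <- function(p, f2) {
  if (!is.numeric(p) || length(p) != 1L || p != round(p) || p < 2)
    stop("`p` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(f2) || length(f2) != 1L || is.na(f2) || f2 < 0)
    stop("`f2` must be a single nonnegative number", call. = FALSE)
  min_n_result(if (f2 == 0) Inf else (p - 1) / (p * f2))
}

#' RMSE of the two-condition difference versus the zero estimator
#'
#' For a two-condition design the quantity of interest is the difference
#' of means.  The sample-mean difference is unbiased with root MSE
#' \eqn{\sqrt{2\sigma^2/n}}; the zero estimator declares the effect
#' identically 0, so its error is constant at \eqn{|\delta|}, the true
#' difference.
#'
#' @param env a two-condition \code{\link{design_environment}} with
#'   \code{n} and \code{sigma}.
#' @param true_difference the true effect \eqn{\delta}, in DV units.
#' @return List with \code{rmse_sm} and \code{rmse_zero}, in DV units.
#' @examples
#' difference_rmse_two_conditions(
#'   design_environment(2, 8, 300), true_difference = 40)
#' @export
difference_rmse_two_conditions <- function(env, true_difference) {
  needs_env(env, c("p", "n", "sigma"))
  if (env$p != 2)
    stop("the difference RMSE is defined for p = 2 designs", call. = FALSE)
  list(rmse_sm = sqrt(2 * env$sigma^2 / env$n),
       rmse_zero = abs(true_difference))
}

#' Full closed-form accuracy report for an environment
#'
#' Collects the MSEs of the three estimators, the bias/variance split of
#' the random estimator, the MSE ratios relative to sample means, and
#' both minimum-sample-size thresholds.
#'
#' @inheritParams mse_sample_means
#' @return An object of class \code{"accuracy_report"} (a list).
#' @examples
#' accuracy_report(design_environment(4, 10, 100, f2 = 0.05))
#' @export
accuracy_report <- function(env) {
  needs_env(env, c("p", "n", "sigma", "f2"))
  sm <- mse_sample_means(env)
  z <- mse_zero(env)
  re <- mse_random(env)
  structure(
    list(
      p = env$p, n = env$n, sigma = env$sigma, f2 = env$f2,
      mse_sample_means = sm,
      mse_zero = z,
      mse_random = re$total,
      random_bias_sq = re$bias_sq,
      random_variance = re$variance,
      ratio_re_sm = re$total / sm,
      ratio_z_sm = z / sm,
      threshold_n_random = min_n_random(env$p, env$f2)$threshold,
      threshold_n_zero = min_n_zero(env$p, env$f2)$threshold
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy report (p = %d, n = %d, sigma = %g, f2 = %g)\n",
              x$p, x$n, x$sigma, x$f2))
  cat(sprintf("  MSE sample means : %.4g\n", x$mse_sample_means))
  cat(sprintf("  MSE zero         : %.4g  (ratio to sm %.3f)\n",
              x$mse_zero, x$ratio_z_sm))
  cat(sprintf("  MSE random       : %.4g  (ratio to sm %.3f)\n",
              x$mse_random, x$ratio_re_sm))
  cat(sprintf("    = bias^2 %.4g + variance %.4g\n",
              x$random_bias_sq, x$random_variance))
  cat(sprintf("  min n vs random  : threshold %.4g\n", x$threshold_n_random))
  cat(sprintf("  min n vs zero    : threshold %.4g\n", x$threshold_n_zero))
  invisible(x)
}
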