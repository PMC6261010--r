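# One-way ANOVA power through the noncentral F distribution, and the
# power reached at the minimal-accuracy sample size.

#' Power of the one-way ANOVA F test
#'
#' Power is \eqn{P(F' \ge F_{crit})} where \eqn{F_{crit}} is the
#' upper-\eqn{\alpha} quantile of the central F distribution with
#' \eqn{(p-1,\; p(n-1))} degrees of freedom and \eqn{F'} is noncentral F
#' with the same degrees of freedom and noncentrality
#' \eqn{\lambda = f^2 N} with \eqn{N = p n} (Cohen's convention; note
#' that \eqn{\lambda = f^2 n} variants exist in the literature).
#'
#' @param p number of conditions (at least 2).
#' @param n per-condition sample size (with \eqn{p(n-1) > 0}).
#' @param f2 nonnegative effect size.
#' @param alpha type-I error rate in (0, 1); default 0.05.
#' @return Power in (0, 1); equals \code{alpha} when \code{f2 = 0}.
#' @examples
#' anova_power(p = 4, n = 10, f2 = 0.05)
#' @export
anova_power <- function(p, n, f2, alpha = 0.05) {
  if (!is.numeric(p) || length(p) != 1L || p != round(p) || p < 2)
    stop("`p` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 1)
    stop("`n` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(f2) || length(f2) != 1L || is.na(f2) || f2 < 0)
    stop("`f2` must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  df2 <- p * (n - 1)
  if (df2 == 0)
    stop("the F test is undefined at n = 1 (zero error df)", call. = FALSE)
  fcrit <- stats::qf(1 - alpha, df1 = p - 1, df2 = df2)
  stats::pf(fcrit, df1 = p - 1, df2 = df2, ncp = f2 * p * n,
            lower.tail = FALSE)
}

#' Minimum per-condition n reaching a target power
#'
#' Smallest integer n with \code{\link{anova_power}} at least
#' \code{target_power}, found by doubling a bracket from n = 2 and then
#' bisecting.  \code{f2 = 0} cannot exceed power \eqn{\alpha}; that case
#' returns \code{Inf} as an unreachable-power signal.
#'
#' @inheritParams anova_power
#' @param target_power desired power in (0, 1).
#' @param n_max search cap (default 1e7); exceeding it is an error.
#' @return Integer n, or \code{Inf} when \code{f2 = 0}.
#' @examples
#' min_n_for_power(p = 4, f2 = 0.0625, target_power = 0.5)
#' @export
min_n_for_power <- function(p, f2, alpha = 0.05, target_power,
                            n_max = 1e7) {
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      is.na(target_power) || target_power <= 0 || target_power >= 1)
    stop("`target_power` must be in (0, 1)", call. = FALSE)
  if (f2 == 0) {
    if (target_power > alpha) return(Inf)
  }
  # bracket [lo, hi] with power(hi) >= target
  hi <- 2L
  while (anova_power(p, hi, f2, alpha) < target_power) {
    hi <- hi * 2L
    if (hi > n_max)
      stop("no n <= ", n_max, " reaches the target power", call. = FALSE)
  }
  lo <- 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (anova_power(p, mid, f2, alpha) >= target_power) hi <- mid
    else lo <- mid
  }
  if (anova_power(p, lo, f2, alpha) >= target_power) lo else hi
}

#' ANOVA power at the minimal-accuracy sample size
#'
#' Evaluates \code{\link{anova_power}} at the smallest n for which sample
#' means are at least as accurate as the random estimator
#' (\code{\link{min_n_random}}).  Values well above \eqn{\alpha} show
#' that a design can be non-trivially powered while its sample means are
#' still less accurate than a nonsense benchmark.
#'
#' @inheritParams anova_power
#' @return Power in (0, 1) at \code{n = min_n_random(p, f2)$min_n}.
#' @examples
#' power_at_minimal_accuracy(p = 4, f2 = 0.05)
#' @export
power_at_minimal_accuracy <- function(p, f2, alpha = 0.05) {
  if (!is.numeric(f2) || length(f2) != 1L || is.na(f2) || f2 <= 0)
    stop("`f2` must be a single positive number", call. = FALSE)
  anova_power(p, min_n_random(p, f2)$min_n, f2, alpha)
}
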