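# Estimators of condition means: sample means, the zero estimator,
# the shrinkage-scaled random estimator, and hierarchical Bayes.

new_estimates <- function(estimator, estimates, labels,
                          b = NULL, a = NULL, seed = NULL, extra = NULL) {
  names(estimates) <- labels
  structure(
    c(list(estimator = estimator, estimates = estimates,
           b = b, a = a, seed = seed), extra),
    class = "mb_estimates"
  )
}

#' @export
print.mb_estimates <- function(x, ...) {
  cat("Estimates (", x$estimator, "):\n", sep = "")
  print(x$estimates)
  if (!is.null(x$b)) cat("  scale b:", format(x$b), "\n")
  invisible(x)
}

#' Per-condition sample means
#'
#' @param data a \code{\link{condition_sample}}.
#' @return An \code{mb_estimates} object whose estimates are the
#'   condition sample means.
#' @export
sample_means <- function(data) {
  stopifnot(inherits(data, "condition_sample"))
  new_estimates("sample_mean", data$sample_means, data$labels)
}

#' The zero estimator: complete pooling to the grand mean
#'
#' Assigns the grand mean of all p*n observations to every condition, so
#' the implied estimate of every treatment effect is identically zero.  A
#' deliberately uninformative benchmark: sample means whose expected
#' squared error exceeds this estimator's are hard to take seriously.
#'
#' @param data a \code{\link{condition_sample}}.
#' @return An \code{mb_estimates} object with all entries equal to the
#'   grand mean.
#' @export
zero_estimate <- function(data) {
  stopifnot(inherits(data, "condition_sample"))
  new_estimates("zero", rep(data$grand_mean, data$p), data$labels)
}

#' Draw the random coefficients of the random estimator
#'
#' Independent uniform draws on \eqn{[-1, 1]}, one per condition.  The
#' draw is fixed at assignment time: coefficients are never re-shuffled to
#' fit the data.  The support \eqn{[-1,1]} is a normalisation only — any
#' bounded interval symmetric about 0 gives the identical estimator after
#' scaling by b.
#'
#' @param p number of conditions (at least 2).
#' @param seed integer RNG seed, recorded for provenance; \code{NULL}
#'   draws from the current RNG state.
#' @return An object of class \code{"random_coefficients"}: list with
#'   \code{a} (length-p numeric in \eqn{[-1,1]}) and \code{seed}.
#' @examples
#' draw_random_coefficients(4, seed = 1)
#' @export
draw_random_coefficients <- function(p, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p != round(p) || p < 2)
    stop("`p` must be a single integer >= 2", call. = FALSE)
  a <- if (is.null(seed)) stats::runif(p, -1, 1)
       else withr::with_seed(seed, stats::runif(p, -1, 1))
  random_coefficients(a, seed = seed)
}

#' @param a numeric vector of coefficients in \eqn{[-1,1]}.
#' @rdname draw_random_coefficients
#' @export
random_coefficients <- function(a, seed = NULL) {
  if (!is.numeric(a) || length(a) < 2 || anyNA(a) || any(abs(a) > 1))
    stop("coefficients must be numeric in [-1, 1], length >= 2",
         call. = FALSE)
  structure(list(a = as.numeric(a), seed = seed),
            class = "random_coefficients")
}

#' Least-squares shrinkage scale of the random estimator
#'
#' Given coefficients \eqn{a_i} and balanced data with deviations
#' \eqn{\alpha_i = \bar y_i - \bar G}, computes the scalar
#' \deqn{b = \left(p - \sqrt{p(p-1)}\right)
#'       \frac{\sum_i a_i \alpha_i}{\sum_i a_i^2}.}
#' b calibrates the random pattern to the scale of the observed
#' deviations with optimal shrinkage; it can be negative, in which case
#' the random ordering is exactly reversed.
#'
#' @param a a \code{random_coefficients} object or numeric vector.
#' @param data a \code{\link{condition_sample}} with matching p.
#' @return Scalar b, in DV units.
#' @examples
#' d <- condition_sample_from_means(c(593, 626, 630, 756))
#' shrinkage_scale(c(-.190, -.973, .823, .600), d)  # ~21.5
#' @export
shrinkage_scale <- function(a, data) {
  stopifnot(inherits(data, "condition_sample"))
  av <- if (inherits(a, "random_coefficients")) a$a else a
  if (length(av) != data$p)
    stop("coefficient length ", length(av), " does not match p = ",
         data$p, call. = FALSE)
  ss <- sum(av^2)
  if (ss == 0)
    stop("degenerate coefficients: sum of squares is zero", call. = FALSE)
  p <- data$p
  (p - sqrt(p * (p - 1))) * sum(av * data$deviations) / ss
}

#' The shrinkage-scaled random estimator of condition means
#'
#' Estimates condition i's mean as \eqn{\bar G + b a_i}: a random pattern
#' (which conditions are high or low, and by how much, is decided by the
#' uniform draws \eqn{a_i}) put on a data-calibrated scale by the
#' shrinkage coefficient b from \code{\link{shrinkage_scale}}.  The
#' estimator scrambles the relations among conditions — exactly the
#' information of scientific interest — while retaining the scale of the
#' data, which makes it a demanding benchmark for sample-mean accuracy.
#'
#' @param data a \code{\link{condition_sample}}.
#' @param a optional \code{random_coefficients} (or numeric vector); when
#'   omitted a fresh draw is made using \code{seed}.
#' @param seed integer seed for the coefficient draw when \code{a} is
#'   missing.
#' @return An \code{mb_estimates} object recording the estimates, b and
#'   the coefficients used.
#' @examples
#' d <- condition_sample_from_means(c(593, 626, 630, 756))
#' random_estimate(d, a = c(-.190, -.973, .823, .600))
#' @export
random_estimate <- function(data, a = NULL, seed = NULL) {
  stopifnot(inherits(data, "condition_sample"))
  if (is.null(a)) a <- draw_random_coefficients(data$p, seed = seed)
  if (!inherits(a, "random_coefficients")) a <- random_coefficients(a)
  b <- shrinkage_scale(a, data)
  new_estimates("random", data$grand_mean + b * a$a, data$labels,
                b = b, a = a$a, seed = a$seed)
}

#' Hierarchical-Bayes shrinkage estimates of condition means
#'
#' Fits the two-level normal model
#' \deqn{y_{k,i} \sim N(\mu^* + \alpha_i, \sigma^2), \quad
#'       \alpha_i \sim N(0, \tau^2),}
#' with a flat prior on \eqn{\mu^*} and the noninformative prior
#' \eqn{\pi(\sigma^2) \propto 1/\sigma^2} (flat on \eqn{\log\sigma^2}),
#' by a Gibbs sampler with conjugate conditional updates.  The returned
#' estimates are posterior means of \eqn{\mu^* + \alpha_i}; they lie
#' between each sample mean and the grand mean (shrinkage), pooling scale
#' information across conditions to reduce total squared error.
#'
#' The prior scale \eqn{\tau} (\code{prior_sd}) is a fixed hyperparameter
#' of the model, in DV units.  The default is the observed SD of the
#' condition sample means — an empirical calibration that adapts the
#' amount of pooling to the apparent between-condition spread; it is
#' always user-overridable.  \eqn{\tau \to 0} gives complete pooling (the
#' grand mean everywhere); \eqn{\tau \to \infty} recovers the sample
#' means.
#'
#' @param data a \code{\link{condition_sample}}.
#' @param prior_sd positive SD \eqn{\tau} of the condition-effect prior;
#'   default \code{sd(sample means)}.
#' @param draws total Gibbs iterations (default 4000).
#' @param burn_in iterations discarded from the front (default 1000).
#' @param seed integer seed; required for reproducible chains.
#' @return An \code{mb_estimates} object; the element \code{ess} holds
#'   the per-condition effective sample size of the retained chains.
#' @examples
#' d <- condition_sample(c(rnorm(10, 600, 50), rnorm(10, 650, 50)),
#'                       rep(c("a", "b"), each = 10))
#' hb_estimate(d, seed = 1)
#' @export
hb_estimate <- function(data, prior_sd = NULL, draws = 4000L,
                        burn_in = 1000L, seed = NULL) {
  stopifnot(inherits(data, "condition_sample"))
  if (is.null(prior_sd)) prior_sd <- stats::sd(data$sample_means)
  if (!is.numeric(prior_sd) || length(prior_sd) != 1L ||
      !is.finite(prior_sd) || prior_sd <= 0)
    stop("`prior_sd` must be a single positive number", call. = FALSE)
  if (draws <= burn_in || burn_in < 0)
    stop("need draws > burn_in >= 0", call. = FALSE)

  run <- function() {
    p <- data$p; n <- data$n; N <- n * p
    y <- data$observations                      # n x p
    ybar <- data$sample_means
    tau2 <- prior_sd^2
    # init at method-of-moments values
    mu <- data$grand_mean
    alpha <- data$deviations
    sigma2 <- max(stats::var(as.vector(y)), .Machine$double.eps)
    keep <- draws - burn_in
    chain <- matrix(NA_real_, nrow = keep, ncol = p)
    for (t in seq_len(draws)) {
      # mu | alpha, sigma2: flat prior
      mu <- stats::rnorm(1, mean(sweep(y, 2, alpha)), sqrt(sigma2 / N))
      # alpha_i | mu, sigma2: conjugate normal
      prec <- n / sigma2 + 1 / tau2
      m <- (n / sigma2) * (ybar - mu) / prec
      alpha <- stats::rnorm(p, m, sqrt(1 / prec))
      # sigma2 | mu, alpha: scaled inverse chi-square from 1/sigma2 prior
      ss <- sum(sweep(y, 2, mu + alpha)^2)
      sigma2 <- ss / stats::rchisq(1, df = N)
      if (!is.finite(sigma2) || sigma2 <= 0)
        stop("Gibbs sampler reached a degenerate variance state",
             call. = FALSE)
      if (t > burn_in) chain[t - burn_in, ] <- mu + alpha
    }
    chain
  }
  chain <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  new_estimates("hierarchical_bayes", colMeans(chain), data$labels,
                seed = seed,
                extra = list(prior_sd = prior_sd,
                             draws = draws, burn_in = burn_in,
                             ess = apply(chain, 2, ess_chain)))
}

# effective sample size from the initial-positive-sequence estimate of
# the autocorrelation time
ess_chain <- function(x) {
  m <- length(x)
  if (stats::var(x) == 0) return(m)
  rho <- stats::acf(x, lag.max = min(m - 1L, 200L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  m / (1 + 2 * sum(rho))
}
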