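#' Describe a balanced one-way design environment
#'
#' An environment is the planning truth of a balanced between-condition
#' experiment: the number of conditions \code{p}, the per-condition sample
#' size \code{n}, the common within-condition standard deviation
#' \code{sigma}, and the separation of the true condition means, expressed
#' either directly as a mean vector \code{mu} or as an effect size
#' (Cohen's \eqn{f^2} or \eqn{R^2}).
#'
#' The effect size may be supplied in any one of three equivalent ways:
#' \code{mu} together with \code{sigma}, \code{f2}, or \code{r2}.  When more
#' than one is supplied they must agree (relative tolerance \code{1e-10});
#' disagreement is an error rather than a silent preference.
#'
#' @param p integer, number of conditions (at least 2).
#' @param n integer, per-condition sample size; may be omitted for pure
#'   effect-size queries.
#' @param sigma positive common within-condition SD, in the units of the
#'   dependent variable (e.g. ms for response times).
#' @param mu optional numeric vector of length \code{p} of true condition
#'   means, in DV units.
#' @param f2 optional nonnegative Cohen noncentrality effect size.
#' @param r2 optional proportion of variance in \eqn{[0, 1)} accounted for
#'   by the condition structure.
#'
#' @return An object of class \code{"design_env"}: a list with elements
#'   \code{p}, \code{n}, \code{sigma}, \code{mu} and \code{f2} (\code{f2}
#'   is \code{NULL} only when no effect-size information was given).
#' @examples
#' design_environment(p = 4, n = 10, sigma = 100,
#'                    mu = c(600, 620, 640, 660))
#' design_environment(p = 5, f2 = 0.05)
#' @export
design_environment <- function(p, n = NULL, sigma = NULL, mu = NULL,
                               f2 = NULL, r2 = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p != round(p) || p < 2)
    stop("`p` must be a single integer >= 2", call. = FALSE)
  p <- as.integer(p)
  if (!is.null(n)) {
    if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 1)
      stop("`n` must be a single integer >= 1", call. = FALSE)
    n <- as.integer(n)
  }
  if (!is.null(sigma)) {
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
        sigma <= 0)
      stop("`sigma` must be a single positive number", call. = FALSE)
  }
  if (!is.null(mu)) {
    if (!is.numeric(mu) || length(mu) != p || anyNA(mu))
      stop("`mu` must be a numeric vector of length p", call. = FALSE)
    if (is.null(sigma))
      stop("`sigma` is required when `mu` is supplied", call. = FALSE)
  }

  # resolve f2 from every channel supplied and demand consistency
  candidates <- list()
  if (!is.null(mu)) candidates$mu <- f2_from_means(mu, sigma)
  if (!is.null(f2)) {
    if (!is.numeric(f2) || length(f2) != 1L || !is.finite(f2) || f2 < 0)
      stop("`f2` must be a single nonnegative number", call. = FALSE)
    candidates$f2 <- f2
  }
  if (!is.null(r2)) candidates$r2 <- f2_from_r2(r2)

  f2_val <- NULL
  if (length(candidates)) {
    vals <- unlist(candidates)
    ref <- vals[[1L]]
    tol <- 1e-10 * max(1, abs(ref))
    if (any(abs(vals - ref) > tol))
      stop("inconsistent effect-size specification: ",
           paste(sprintf("%s=%.12g", names(vals), vals), collapse = ", "),
           call. = FALSE)
    f2_val <- ref
  }

  structure(
    list(p = p, n = n, sigma = sigma, mu = mu, f2 = f2_val),
    class = "design_env"
  )
}

#' @export
print.design_env <- function(x, ...) {
  cat("Design environment:", x$p, "conditions")
  if (!is.null(x$n)) cat(", n =", x$n, "per condition")
  cat("\n")
  if (!is.null(x$sigma)) cat("  sigma:", x$sigma, "\n")
  if (!is.null(x$mu)) cat("  true means:", paste(x$mu, collapse = ", "), "\n")
  if (!is.null(x$f2)) cat("  Cohen f2:", format(x$f2), "\n")
  invisible(x)
}

#' Cohen's f-squared from true condition means
#'
#' Computes the noncentrality effect size
#' \deqn{f^2 = \frac{1}{p}\sum_i (\mu_i - \mu^*)^2 / \sigma^2,}
#' where \eqn{\mu^*} is the (unweighted) mean of the condition means — the
#' population grand mean of a balanced design.
#'
#' @param mu numeric vector of at least two true condition means.
#' @param sigma positive common within-condition SD.
#' @return Nonnegative scalar \eqn{f^2}.
#' @examples
#' f2_from_means(c(600, 620, 640, 660), 100)  # 0.05
#' @export
f2_from_means <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) < 2 || anyNA(mu))
    stop("`mu` must contain at least 2 numeric means", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  mean((mu - mean(mu))^2) / sigma^2
}

#' Convert between f-squared and R-squared
#'
#' \eqn{f^2 = R^2/(1-R^2)} and its inverse \eqn{R^2 = f^2/(1+f^2)}.
#'
#' @param r2 proportion of variance in \eqn{[0, 1)}.
#' @return Nonnegative scalar.
#' @examples
#' f2_from_r2(0.5)       # 1
#' r2_from_f2(0.0625)    # ~0.0588, the "medium" calibration
#' @export
f2_from_r2 <- function(r2) {
  if (!is.numeric(r2) || length(r2) != 1L || is.na(r2) || r2 < 0 || r2 >= 1)
    stop("`r2` must be a single number in [0, 1)", call. = FALSE)
  r2 / (1 - r2)
}

#' @param f2 nonnegative effect size.
#' @rdname f2_from_r2
#' @export
r2_from_f2 <- function(f2) {
  if (!is.numeric(f2) || length(f2) != 1L || is.na(f2) || f2 < 0)
    stop("`f2` must be a single nonnegative number", call. = FALSE)
  f2 / (1 + f2)
}

#' Conventional f-squared calibration values
#'
#' The conventional small/medium/large calibration of \eqn{f^2}
#' (0.01, 0.0625 and 0.16), analogous to 0.2/0.5/0.8 for Cohen's d.
#'
#' @return Named numeric vector with elements \code{small}, \code{medium},
#'   \code{large}.
#' @examples
#' cohen_f2()["medium"]
#' @export
cohen_f2 <- function() {
  c(small = 0.01, medium = 0.0625, large = 0.16)
}
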