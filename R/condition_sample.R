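#' Balanced observed data for a one-way design
#'
#' Bundles the raw observations of a balanced p-condition experiment with
#' the derived quantities every estimator needs: per-condition sample
#' means \eqn{\bar y_i}, the grand mean \eqn{\bar G} over all p*n
#' observations, and the deviations \eqn{\alpha_i = \bar y_i - \bar G}
#' (which sum to zero under balance).
#'
#' @param values numeric vector of observations.
#' @param condition vector of condition labels, same length as
#'   \code{values}; condition order is first-appearance order.
#' @return An object of class \code{"condition_sample"}: a list with
#'   \code{labels}, \code{observations} (an n-by-p matrix, one column per
#'   condition), \code{n}, \code{p}, \code{sample_means},
#'   \code{grand_mean} and \code{deviations}.
#' @examples
#' condition_sample(c(1, 3, 2, 4), condition = c("a", "a", "b", "b"))
#' @export
condition_sample <- function(values, condition) {
  if (!is.numeric(values) || anyNA(values))
    stop("`values` must be numeric with no missing entries", call. = FALSE)
  if (length(condition) != length(values))
    stop("`condition` and `values` must have equal length", call. = FALSE)
  condition <- as.character(condition)
  labels <- unique(condition)
  p <- length(labels)
  if (p < 2)
    stop("need at least 2 conditions", call. = FALSE)
  counts <- table(factor(condition, levels = labels))
  if (length(unique(as.integer(counts))) != 1L)
    stop("unbalanced design: counts per condition are ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  n <- as.integer(counts[[1L]])
  obs <- vapply(labels, function(l) values[condition == l], numeric(n))
  obs <- matrix(obs, nrow = n, ncol = p, dimnames = list(NULL, labels))
  new_condition_sample(obs)
}

# internal: build from an n x p observation matrix (columns = conditions)
new_condition_sample <- function(obs) {
  means <- colMeans(obs)
  g <- mean(obs)
  structure(
    list(labels = colnames(obs), observations = obs,
         n = nrow(obs), p = ncol(obs),
         sample_means = means, grand_mean = g, deviations = means - g),
    class = "condition_sample"
  )
}

#' Balanced sample with prescribed condition means
#'
#' Builds a degenerate \code{condition_sample} whose observations within a
#' condition all equal the stated mean.  Useful for computing estimators
#' directly from a printed table of sample means: under balance the zero
#' and random estimators depend on the data only through the condition
#' means.
#'
#' @param means numeric vector of condition means.
#' @param n per-condition sample size to record (default 2).
#' @param labels optional condition labels.
#' @return A \code{condition_sample}.
#' @examples
#' condition_sample_from_means(c(593, 626, 630, 756))
#' @export
condition_sample_from_means <- function(means, n = 2L, labels = NULL) {
  if (!is.numeric(means) || length(means) < 2 || anyNA(means))
    stop("`means` must contain at least 2 numeric values", call. = FALSE)
  if (is.null(labels)) labels <- paste0("c", seq_along(means))
  obs <- matrix(rep(means, each = n), nrow = n,
                dimnames = list(NULL, labels))
  new_condition_sample(obs)
}

#' @export
print.condition_sample <- function(x, ...) {
  cat("Balanced condition sample: p =", x$p, ", n =", x$n,
      "per condition\n")
  cat("  sample means:",
      paste(sprintf("%s=%.4g", x$labels, x$sample_means), collapse = ", "),
      "\n")
  cat("  grand mean:", format(x$grand_mean), "\n")
  invisible(x)
}

#' @export
as.data.frame.condition_sample <- function(x, ...) {
  data.frame(
    condition = rep(x$labels, each = x$n),
    value = as.vector(x$observations),
    stringsAsFactors = FALSE
  )
}
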