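# Monte-Carlo engine: synthetic data generation, estimator comparison,
# and the heterogeneous-variance robustness study.

noise_families <- c("normal", "uniform", "shifted_exponential")

# one matrix of iid noise with mean 0 and SD 1, by family
std_noise <- function(nvals, family) {
  switch(family,
    normal = stats::rnorm(nvals),
    uniform = stats::runif(nvals, -sqrt(3), sqrt(3)),
    shifted_exponential = stats::rexp(nvals) - 1,
    stop("unknown noise family: ", family, call. = FALSE)
  )
}

#' Generate one balanced synthetic dataset from an environment
#'
#' Draws n observations per condition with location \eqn{\mu_i} and noise
#' from the chosen family, scaled so the within-condition SD equals
#' \code{sigma} (or the per-condition values).  Uniform noise is centered
#' with half-width \eqn{\sqrt3\,\sigma}; exponential noise is shifted to
#' mean 0 and scaled to SD \eqn{\sigma}, so the effect size of the
#' environment is preserved across families.
#'
#' @param env a \code{\link{design_environment}} with \code{mu}, \code{n},
#'   \code{sigma}.
#' @param noise_family one of \code{"normal"} (default), \code{"uniform"},
#'   \code{"shifted_exponential"}.
#' @param per_condition_sigmas optional length-p vector of positive SDs
#'   overriding the common \code{sigma} (heterogeneity studies).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return A \code{\link{condition_sample}}.
#' @examples
#' env <- design_environment(4, 10, 100, mu = c(600, 620, 640, 660))
#' generate_dataset(env, seed = 1)
#' @export
generate_dataset <- function(env, noise_family = "normal",
                             per_condition_sigmas = NULL, seed = NULL) {
  needs_env(env, c("p", "n", "sigma", "mu"))
  noise_family <- match.arg(noise_family, noise_families)
  sds <- check_sigmas(per_condition_sigmas, env)
  gen <- function() {
    e <- matrix(std_noise(env$n * env$p, noise_family), nrow = env$n)
    obs <- sweep(e, 2, sds, `*`)
    obs <- sweep(obs, 2, env$mu, `+`)
    colnames(obs) <- paste0("c", seq_len(env$p))
    new_condition_sample(obs)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

check_sigmas <- function(per_condition_sigmas, env) {
  if (is.null(per_condition_sigmas)) return(rep(env$sigma, env$p))
  if (!is.numeric(per_condition_sigmas) ||
      length(per_condition_sigmas) != env$p ||
      any(!is.finite(per_condition_sigmas)) ||
      any(per_condition_sigmas <= 0))
    stop("`per_condition_sigmas` must be ", env$p, " positive numbers",
         call. = FALSE)
  per_condition_sigmas
}

#' Monte-Carlo comparison of estimators against the true means
#'
#' Each repetition independently generates a balanced dataset from the
#' environment, computes the requested estimators (with a fresh
#' coefficient draw for the random estimator every repetition — it is
#' the estimator, not one fixed assignment, that is being evaluated) and
#' records the summed squared error \eqn{\sum_i (\hat\mu_i - \mu_i)^2}
#' against the true means.  Averaging the per-repetition summed squared
#' errors estimates each estimator's MSE.
#'
#' The sample-mean, zero and random estimators are evaluated in a
#' vectorised sweep; the hierarchical-Bayes estimator (one Gibbs chain
#' per repetition) is evaluated in a loop and is therefore much slower —
#' request it only at modest \code{reps}.
#'
#' @param env a \code{\link{design_environment}} with \code{mu}, \code{n},
#'   \code{sigma}.
#' @param reps number of repetitions (at least 1).
#' @param seed integer seed; results are a pure function of
#'   (environment, configuration, seed).
#' @param noise_family noise family, as in \code{\link{generate_dataset}}.
#' @param per_condition_sigmas optional per-condition SDs.
#' @param estimators subset of \code{c("sample_mean", "zero", "random",
#'   "hierarchical_bayes")}.
#' @param hb_args list of arguments passed on to \code{\link{hb_estimate}}
#'   when the hierarchical-Bayes estimator is requested.
#' @return An object of class \code{"mb_simulation"}: list with
#'   \code{per_rep_sse} (reps-by-estimators matrix), \code{mean_mse}
#'   (named vector), \code{ratio_of_means} (sample-mean MSE over
#'   random-estimator MSE, when both were run), \code{fraction_sm_worse}
#'   (share of repetitions in which sample means incurred the larger
#'   squared error), and a config echo.
#' @examples
#' env <- design_environment(4, 10, 100, mu = c(600, 620, 640, 660))
#' simulate_mse(env, reps = 1000, seed = 1)
#' @export
simulate_mse <- function(env, reps, seed = NULL, noise_family = "normal",
                         per_condition_sigmas = NULL,
                         estimators = c("sample_mean", "zero", "random"),
                         hb_args = list()) {
  needs_env(env, c("p", "n", "sigma", "mu"))
  noise_family <- match.arg(noise_family, noise_families)
  estimators <- match.arg(
    estimators,
    c("sample_mean", "zero", "random", "hierarchical_bayes"),
    several.ok = TRUE)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1)
    stop("`reps` must be a single integer >= 1", call. = FALSE)
  reps <- as.integer(reps)
  sds <- check_sigmas(per_condition_sigmas, env)

  run <- function() {
    p <- env$p; n <- env$n; mu <- env$mu
    shrink <- p - sqrt(p * (p - 1))
    sse <- matrix(NA_real_, nrow = reps, ncol = length(estimators),
                  dimnames = list(NULL, estimators))
    hb <- "hierarchical_bayes" %in% estimators
    chunk <- max(1L, min(reps, as.integer(2e6 / (n * p))))
    done <- 0L
    while (done < reps) {
      k <- min(chunk, reps - done)
      # k datasets at once: noise array n x p x k
      e <- array(std_noise(n * p * k, noise_family), dim = c(n, p, k))
      e <- e * sds[slice.index(e, 2)]
      ybar <- apply(e, c(2, 3), mean) + mu          # p x k sample means
      g <- colMeans(ybar)                           # grand means, length k
      alpha <- sweep(ybar, 2, g)                    # deviations, p x k
      rows <- done + seq_len(k)
      for (est in estimators) {
        if (est == "sample_mean") {
          sse[rows, est] <- colSums((ybar - mu)^2)
        } else if (est == "zero") {
          sse[rows, est] <- colSums((matrix(g, p, k, byrow = TRUE) - mu)^2)
        } else if (est == "random") {
          a <- matrix(stats::runif(p * k, -1, 1), p, k)
          b <- shrink * colSums(a * alpha) / colSums(a^2)
          est_re <- matrix(g, p, k, byrow = TRUE) +
            sweep(a, 2, b, `*`)
          sse[rows, est] <- colSums((est_re - mu)^2)
        }
      }
      if (hb) {
        for (j in seq_len(k)) {
          obs <- sweep(matrix(e[, , j], n, p), 2, mu, `+`)
          colnames(obs) <- paste0("c", seq_len(p))
          d <- new_condition_sample(obs)
          fit <- do.call(hb_estimate, c(list(data = d), hb_args))
          sse[done + j, "hierarchical_bayes"] <-
            sum((fit$estimates - mu)^2)
        }
      }
      done <- done + k
    }
    sse
  }
  sse <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  mean_mse <- colMeans(sse)
  ratio <- if (all(c("sample_mean", "random") %in% estimators))
    mean_mse[["sample_mean"]] / mean_mse[["random"]] else NA_real_
  frac <- if (all(c("sample_mean", "random") %in% estimators))
    mean(sse[, "sample_mean"] > sse[, "random"]) else NA_real_

  structure(
    list(per_rep_sse = sse, mean_mse = mean_mse,
         ratio_of_means = ratio, fraction_sm_worse = frac,
         config = list(p = env$p, n = env$n, sigma = env$sigma,
                       mu = env$mu, f2 = env$f2,
                       noise_family = noise_family,
                       per_condition_sigmas = per_condition_sigmas,
                       reps = reps, seed = seed,
                       estimators = estimators)),
    class = "mb_simulation"
  )
}

#' @export
print.mb_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte-Carlo comparison: %d reps, p = %d, n = %d, %s noise\n",
              cfg$reps, cfg$p, cfg$n, cfg$noise_family))
  cat("  mean MSE by estimator:\n")
  print(round(x$mean_mse, 2))
  if (!is.na(x$ratio_of_means))
    cat(sprintf("  sample-mean / random MSE ratio: %.3f; sample means worse in %.1f%% of reps\n",
                x$ratio_of_means, 100 * x$fraction_sm_worse))
  invisible(x)
}

#' Robustness of the minimum-n rule to unequal variances
#'
#' For each per-condition SD profile, runs the Monte-Carlo comparison at
#' a sample size just below and just above the random-estimator threshold
#' computed from the average variance
#' (\eqn{\bar\sigma^2 = \mathrm{mean}(\sigma_i^2)}), and reports whether
#' the observed MSE ordering of sample means versus the random estimator
#' agrees with the homogeneous-variance rule on each side.
#'
#' @param base_env a \code{\link{design_environment}} with \code{mu} and
#'   \code{sigma}; its \code{n} is ignored (n is set by the threshold).
#' @param sigma_profiles list of length-p positive SD vectors.
#' @param reps repetitions per run.
#' @param seed integer seed.
#' @param noise_family noise family for the draws.
#' @return Object of class \code{"mb_heterogeneity"}: a data frame with
#'   one row per (profile, side) and columns for n, the two mean MSEs and
#'   whether the ordering agrees with the rule.
#' @export
heterogeneity_study <- function(base_env, sigma_profiles, reps = 10000,
                                seed = NULL, noise_family = "normal") {
  needs_env(base_env, c("p", "sigma", "mu"))
  if (!is.list(sigma_profiles) || !length(sigma_profiles))
    stop("`sigma_profiles` must be a non-empty list of SD vectors",
         call. = FALSE)
  run <- function() {
    out <- list()
    for (i in seq_along(sigma_profiles)) {
      prof <- check_sigmas(sigma_profiles[[i]], base_env)
      sbar2 <- mean(prof^2)
      f2 <- f2_from_means(base_env$mu, sqrt(sbar2))
      thr <- min_n_random(base_env$p, f2)$threshold
      n_below <- max(2L, as.integer(if (floor(thr) < thr) floor(thr)
                                    else thr - 1))
      n_above <- as.integer(ceiling(thr + 1))
      for (side in c("below", "above")) {
        n <- if (side == "below") n_below else n_above
        env <- design_environment(base_env$p, n, sqrt(sbar2),
                                  mu = base_env$mu)
        sim <- simulate_mse(env, reps = reps,
                            noise_family = noise_family,
                            per_condition_sigmas = prof)
        random_better <- sim$mean_mse[["random"]] <
          sim$mean_mse[["sample_mean"]]
        out[[length(out) + 1L]] <- data.frame(
          profile = i, side = side, n = n, threshold = thr, f2 = f2,
          mse_sample_means = sim$mean_mse[["sample_mean"]],
          mse_random = sim$mean_mse[["random"]],
          agrees_with_rule = random_better == (side == "below"))
      }
    }
    do.call(rbind, out)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(res, class = c("mb_heterogeneity", "data.frame"))
}
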