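# Data I/O and the reproducibility presets tying the package to the
# desk-scale worked examples.

#' Read a balanced long-format CSV of observations
#'
#' Expects a UTF-8 CSV with header \code{condition,value}; condition
#' labels are arbitrary strings and the condition ordering of the result
#' is first-appearance order.  The balanced-design check happens on load.
#'
#' @param path path to the CSV file.
#' @return A \code{\link{condition_sample}}.
#' @export
read_condition_csv <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c("character", "character"),
                        check.names = FALSE)
  if (!identical(names(df), c("condition", "value")))
    stop("expected header `condition,value`, found: ",
         paste(names(df), collapse = ","), call. = FALSE)
  vals <- suppressWarnings(as.numeric(df$value))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("non-numeric value at data row ", bad, ": '", df$value[bad], "'",
         call. = FALSE)
  }
  condition_sample(vals, df$condition)
}

#' Write a condition sample as long-format CSV
#'
#' @param data a \code{\link{condition_sample}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_condition_csv <- function(data, path) {
  stopifnot(inherits(data, "condition_sample"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write estimates as CSV or JSON with provenance
#'
#' CSV columns are \code{condition,estimate,estimator}; JSON additionally
#' records the shrinkage scale b, the coefficient draw and the seed when
#' present.
#'
#' @param est an \code{mb_estimates} object.
#' @param path output path; format chosen by extension (\code{.json} or
#'   anything else for CSV).
#' @return \code{path}, invisibly.
#' @export
write_estimates <- function(est, path) {
  stopifnot(inherits(est, "mb_estimates"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(estimator = est$estimator,
           condition = names(est$estimates),
           estimates = unname(est$estimates),
           b = est$b, a = est$a, seed = est$seed),
      path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    utils::write.csv(
      data.frame(condition = names(est$estimates),
                 estimate = unname(est$estimates),
                 estimator = est$estimator),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Run a named desk-scale preset end to end
#'
#' Presets bundle the package's reference analyses:
#' \describe{
#'   \item{\code{worked-example}}{the four-condition response-time sample
#'     with printed means (593, 626, 630, 756) ms and the fixed
#'     coefficient draw (-0.190, -0.973, 0.823, 0.600); reports b and
#'     the random estimates.  The coefficient vector is injected rather
#'     than drawn so the reference numbers are exactly reproducible.}
#'   \item{\code{motivating}}{the two-condition 40 ms effect with n = 8
#'     and sigma in {300, 50, 500} ms; reports the sample-mean-difference
#'     RMSE for each sigma and the constant zero-estimator error.}
#'   \item{\code{fig3}}{the four-condition environment mu = (600, 620,
#'     640, 660) ms, sigma = 100 ms, n = 10, simulated for 10,000
#'     repetitions; reports the MSE ratio and the fraction of repetitions
#'     in which sample means are worse than the random estimator.}
#'   \item{\code{supp-heterogeneity-p3}, \code{supp-heterogeneity-p5}}{
#'     unequal-variance robustness runs at p = 3 and p = 5.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed for the stochastic presets.
#' @param reps repetitions for the simulation presets (default 10000 for
#'   \code{fig3}, 4000 for the heterogeneity presets).
#' @return A named list of the preset's results (JSON-serialisable).
#' @examples
#' run_preset("worked-example")
#' @export
run_preset <- function(name, seed = 1L, reps = NULL) {
  name <- match.arg(name, c("worked-example", "motivating", "fig3",
                            "supp-heterogeneity-p3",
                            "supp-heterogeneity-p5"))
  switch(name,
    "worked-example" = {
      means <- c(593, 626, 630, 756)
      a <- c(-0.190, -0.973, 0.823, 0.600)
      d <- condition_sample_from_means(means, n = 10L)
      est <- random_estimate(d, a = a)
      list(preset = name, sample_means = means, a = a,
           grand_mean = d$grand_mean, b = est$b,
           random_estimates = unname(est$estimates),
           zero_estimates = unname(zero_estimate(d)$estimates))
    },
    "motivating" = {
      sigmas <- c(300, 50, 500)
      rmse <- vapply(sigmas, function(s)
        difference_rmse_two_conditions(
          design_environment(2, 8, s), true_difference = 40)$rmse_sm,
        numeric(1))
      list(preset = name, n = 8, true_difference = 40,
           sigma = sigmas, rmse_sample_mean_difference = rmse,
           zero_estimator_error = 40)
    },
    "fig3" = {
      if (is.null(reps)) reps <- 10000L
      env <- design_environment(4, 10, 100, mu = c(600, 620, 640, 660))
      sim <- simulate_mse(env, reps = reps, seed = seed)
      list(preset = name, seed = seed, reps = reps, f2 = env$f2,
           mean_mse = as.list(sim$mean_mse),
           ratio_of_means = sim$ratio_of_means,
           pct_excess_mse_sm = 100 * (sim$ratio_of_means - 1),
           fraction_sm_worse = sim$fraction_sm_worse,
           closed_form_ratio = mse_sample_means(env) /
             mse_random(env)$total)
    },
    "supp-heterogeneity-p3" = {
      if (is.null(reps)) reps <- 4000L
      base <- design_environment(3, sigma = 100,
                                 mu = c(600, 630, 660), n = 2)
      study <- heterogeneity_study(
        base,
        sigma_profiles = list(c(100, 100, 100), c(50, 100, 200)),
        reps = reps, seed = seed)
      c(list(preset = name, seed = seed, reps = reps),
        as.list(as.data.frame(study)))
    },
    "supp-heterogeneity-p5" = {
      if (is.null(reps)) reps <- 4000L
      base <- design_environment(5, sigma = 100,
                                 mu = c(600, 615, 630, 645, 660), n = 2)
      study <- heterogeneity_study(
        base,
        sigma_profiles = list(rep(100, 5), c(50, 75, 100, 150, 200)),
        reps = reps, seed = seed)
      c(list(preset = name, seed = seed, reps = reps),
        as.list(as.data.frame(study)))
    })
}
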