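test_that("generate_dataset is seed-deterministic with correct moments", {
  env <- fig3_env()
  d1 <- generate_dataset(env, seed = 5)
  d2 <- generate_dataset(env, seed = 5)
  expect_identical(d1$observations, d2$observations)
  expect_equal(d1$p, 4)
  expect_equal(d1$n, 10)
  # near-degenerate noise pins the sample means to mu
  tiny <- generate_dataset(design_environment(4, 10, 1e-9,
                                              mu = env$mu), seed = 1)
  expect_equal(unname(tiny$sample_means), env$mu, tolerance = 1e-6)
  # large-sample SD check per family, pooled across many draws
  for (fam in c("normal", "uniform", "shifted_exponential")) {
    big <- generate_dataset(design_environment(2, 5e5, 100,
                                               mu = c(0, 0)),
                            noise_family = fam, seed = 2)
    expect_equal(sd(as.vector(big$observations)), 100, tolerance = 0.005)
    expect_equal(mean(big$observations), 0, tolerance = 0.5)
  }
  expect_error(generate_dataset(env, noise_family = "cauchy"), "should be")
  expect_error(generate_dataset(env, per_condition_sigmas = c(1, 2)),
               "4 positive")
})

test_that("simulated MSEs agree with the closed forms", {
  env <- fig3_env()
  sim <- simulate_mse(env, reps = 2e4, seed = 31)
  se <- mc_se(sim)
  expect_lt(abs(sim$mean_mse[["sample_mean"]] - mse_sample_means(env)),
            4 * se[["sample_mean"]])
  expect_lt(abs(sim$mean_mse[["zero"]] - mse_zero(env)),
            4 * se[["zero"]])
  expect_lt(abs(sim$mean_mse[["random"]] - mse_random(env)$total),
            4 * se[["random"]])
})

test_that("null environment recovers pure sample-mean variance", {
  env <- design_environment(3, 8, 50, mu = c(500, 500, 500))
  sim <- simulate_mse(env, reps = 2e4, seed = 17,
                      estimators = "sample_mean")
  se <- mc_se(sim)
  expect_lt(abs(sim$mean_mse[["sample_mean"]] - 3 * 50^2 / 8),
            3 * se[["sample_mean"]])
})

test_that("simulation summaries are pure functions of config and seed", {
  env <- fig3_env()
  s1 <- simulate_mse(env, reps = 500, seed = 99)
  s2 <- simulate_mse(env, reps = 500, seed = 99)
  expect_identical(s1$per_rep_sse, s2$per_rep_sse)
  expect_identical(s1$ratio_of_means, s2$ratio_of_means)
  # one repetition degenerates gracefully
  s3 <- simulate_mse(env, reps = 1, seed = 1)
  expect_equal(nrow(s3$per_rep_sse), 1)
  expect_true(all(is.finite(s3$mean_mse)))
})

test_that("sample means lose more often than not below the threshold", {
  env <- fig3_env()   # n = 10 is far below the threshold of ~17.3
  sim <- simulate_mse(env, reps = 2e4, seed = 13)
  expect_gt(sim$fraction_sm_worse, 0.5)
})

test_that("heterogeneous variances do not break the minimum-n ordering", {
  base <- design_environment(3, sigma = 100, mu = c(600, 630, 660), n = 2)
  study <- heterogeneity_study(
    base, sigma_profiles = list(c(100, 100, 100), c(50, 100, 200)),
    reps = 4000, seed = 23)
  expect_equal(nrow(study), 4)
  expect_true(all(study$threshold > 0))
  # well below the threshold the random estimator wins even with strong
  # variance heterogeneity (threshold here is ~13.6; use n = 5)
  env <- design_environment(3, 5, 100, mu = c(600, 630, 660))
  het <- simulate_mse(env, reps = 2e4, seed = 29,
                      per_condition_sigmas = c(50, 100, 200))
  expect_lt(het$mean_mse[["random"]], het$mean_mse[["sample_mean"]])
  # reproducible
  study2 <- heterogeneity_study(
    base, sigma_profiles = list(c(100, 100, 100), c(50, 100, 200)),
    reps = 4000, seed = 23)
  expect_identical(study$mse_random, study2$mse_random)
  expect_error(heterogeneity_study(base, list(), reps = 10), "non-empty")
})
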