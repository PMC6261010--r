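test_that("closed-form MSEs match direct substitution", {
  env <- fig3_env()
  expect_equal(mse_sample_means(env), 4000)
  expect_equal(mse_zero(env), 1000 + 2000)
  mr <- mse_random(env)
  expect_equal(mr$bias_sq, 1500)
  expect_equal(mr$total, mr$bias_sq + mr$variance)
  expect_equal(mr$total, 2823.1, tolerance = 1e-4)
  # halving/doubling behaviour in n
  env2 <- design_environment(4, 20, 100, mu = c(600, 620, 640, 660))
  expect_equal(mse_sample_means(env2), 2000)
  # f2 = 0: zero estimator dominates, random estimator is unbiased
  null_env <- design_environment(4, 10, 100, f2 = 0)
  expect_lt(mse_zero(null_env), mse_sample_means(null_env))
  expect_equal(mse_random(null_env)$bias_sq, 0)
})

test_that("minimum-n thresholds match reference values and algebra", {
  r5 <- min_n_random(5, 0.05)
  expect_equal(round(r5$threshold, 1), 17.9)
  expect_equal(r5$min_n, 18L)
  z5 <- min_n_zero(5, 0.05)
  expect_equal(z5$threshold, 16)
  expect_equal(z5$min_n, 16L)       # exact MSE tie counts as acceptable
  expect_equal(min_n_random(2, 0.05)$min_n, 15L)
  expect_equal(min_n_zero(2, 0.01)$min_n, 50L)
  # huge effects need no benchmark protection
  expect_equal(min_n_random(4, 10)$min_n, 1L)
  # f2 = 0: tagged never, not an exception
  expect_identical(min_n_random(3, 0)$threshold, Inf)
  expect_identical(min_n_zero(3, 0)$min_n, Inf)
})

test_that("MSE crossings happen exactly at the continuous thresholds", {
  for (p in 2:10) {
    for (f2 in c(0.01, 0.03, 0.05, 0.1, 0.2)) {
      # random-estimator boundary
      nstar <- min_n_random(p, f2)$threshold
      env <- design_environment(p, 2, 37, f2 = f2)
      env$n <- nstar                      # n treated as continuous here
      expect_equal(mse_random(env)$total, mse_sample_means(env),
                   tolerance = 1e-9)
      # zero-estimator boundary
      nz <- min_n_zero(p, f2)$threshold
      env$n <- nz
      expect_equal(mse_zero(env), mse_sample_means(env),
                   tolerance = 1e-9)
      # the two thresholds sit in a fixed ratio
      expect_equal(nstar / nz, sqrt(p / (p - 1)), tolerance = 1e-12)
    }
  }
})

test_that("benchmark MSEs are monotone in f2 and scale as sigma^2", {
  grid <- expand.grid(p = c(2, 4, 6), n = c(5, 20), sigma = c(50, 100))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    f2s <- seq(0.01, 0.2, by = 0.01)
    mz <- vapply(f2s, function(f2)
      mse_zero(design_environment(g$p, g$n, g$sigma, f2 = f2)), numeric(1))
    mr <- vapply(f2s, function(f2)
      mse_random(design_environment(g$p, g$n, g$sigma, f2 = f2))$total,
      numeric(1))
    expect_true(all(diff(mz) > 0))
    expect_true(all(diff(mr) > 0))
    # sigma^2 scaling
    e1 <- design_environment(g$p, g$n, g$sigma, f2 = 0.05)
    e2 <- design_environment(g$p, g$n, 2 * g$sigma, f2 = 0.05)
    expect_equal(mse_random(e2)$total, 4 * mse_random(e1)$total)
    expect_equal(mse_zero(e2), 4 * mse_zero(e1))
    expect_equal(mse_sample_means(e2), 4 * mse_sample_means(e1))
  }
})

test_that("two-condition difference RMSE matches the reference triplet", {
  for (case in list(c(300, 150), c(50, 25), c(500, 250))) {
    env <- design_environment(2, 8, case[1])
    r <- difference_rmse_two_conditions(env, true_difference = 40)
    expect_equal(r$rmse_sm, case[2])
    expect_equal(r$rmse_zero, 40)
  }
  expect_error(
    difference_rmse_two_conditions(design_environment(3, 8, 300), 40),
    "p = 2")
})

test_that("accuracy_report is internally consistent", {
  rep_ <- accuracy_report(fig3_env())
  expect_equal(rep_$mse_random, rep_$random_bias_sq + rep_$random_variance)
  expect_equal(rep_$ratio_re_sm, rep_$mse_random / rep_$mse_sample_means)
  expect_equal(rep_$threshold_n_random / rep_$threshold_n_zero,
               sqrt(4 / 3))
  expect_gt(rep_$mse_sample_means, 0)
})
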