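test_that("condition_sample derives balanced summaries consistently", {
  d <- condition_sample(c(1, 3, 2, 4), c("a", "a", "b", "b"))
  expect_equal(d$sample_means, c(a = 2, b = 3))
  expect_equal(d$grand_mean, 2.5)
  expect_equal(sum(d$deviations), 0)
  expect_error(condition_sample(c(1, 2, 3), c("a", "a", "b")),
               "unbalanced")
  expect_error(condition_sample(1:4, rep("a", 4)), "at least 2")
})

test_that("sample_means and zero_estimate recover the reference sample", {
  d <- worked_sample()
  expect_equal(unname(sample_means(d)$estimates), worked_means)
  z <- zero_estimate(d)
  expect_equal(unname(z$estimates), rep(651.25, 4))
  # implied estimate of every pairwise effect is identically zero
  expect_equal(diff(z$estimates), c(0, 0, 0), ignore_attr = TRUE)
  # constant data
  dc <- condition_sample(rep(7, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(sample_means(dc)$estimates), rep(7, 3))
})

test_that("coefficient draws are reproducible, bounded and centered", {
  a1 <- draw_random_coefficients(4, seed = 99)
  a2 <- draw_random_coefficients(4, seed = 99)
  expect_identical(a1$a, a2$a)
  expect_true(all(abs(a1$a) <= 1))
  expect_error(draw_random_coefficients(1, seed = 1), ">= 2")
  # CLT bound on the mean of many uniform[-1,1] draws
  big <- withr::with_seed(5, runif(1e6, -1, 1))
  expect_lt(abs(mean(big)), 3 * (1 / sqrt(3)) / 1000)
})

test_that("shrinkage scale matches reference and hand arithmetic", {
  d <- worked_sample()
  expect_equal(round(shrinkage_scale(worked_a, d), 1), 21.5)
  # all deviations zero: numerator vanishes
  dc <- condition_sample_from_means(rep(650, 4))
  expect_equal(shrinkage_scale(worked_a, dc), 0)
  # hand-computed case: a and alpha proportional
  dh <- condition_sample_from_means(600 + c(10, -10, 10, -10))
  expect_equal(shrinkage_scale(c(1, -1, 1, -1), dh), (4 - sqrt(12)) * 10)
  expect_error(shrinkage_scale(c(0, 0, 0, 0), d), "degenerate")
  expect_error(shrinkage_scale(c(1, -1), d), "match")
})

test_that("random_estimate reproduces the reference estimates", {
  d <- worked_sample()
  est <- random_estimate(d, a = worked_a)
  expect_equal(round(unname(est$estimates)), c(647, 630, 669, 664))
  expect_equal(round(est$b, 1), 21.5)
  # b = 0 degenerates to the zero estimator
  dc <- condition_sample_from_means(rep(650, 4))
  expect_equal(unname(random_estimate(dc, a = worked_a)$estimates),
               rep(650, 4))
})

test_that("random estimates are an affine map of the coefficients", {
  d <- noisy_sample(p = 5, seed = 3)
  for (s in 1:25) {
    a <- draw_random_coefficients(5, seed = s)
    est <- random_estimate(d, a = a)
    # mean identity and order: order follows a when b > 0, reverses when b < 0
    expect_equal(mean(est$estimates), d$grand_mean + est$b * mean(a$a))
    expected_order <- if (est$b >= 0) order(a$a) else rev(order(a$a))
    expect_equal(order(est$estimates), expected_order)
  }
})

test_that("two-condition random estimates never scramble the order", {
  d <- noisy_sample(p = 2, n = 8, sigma = 50, seed = 9,
                    mu = c(680, 720))
  for (s in 1:50) {
    est <- random_estimate(d, seed = s)
    expect_equal(order(est$estimates), order(d$sample_means))
  }
})

test_that("random-estimate order decorrelates from the data as p grows", {
  # the scale b can reverse the random ordering to fit the data, so the
  # rank correlation with the sample means stays nonnegative on average;
  # it is 1 at p = 2 and decays toward zero as p grows
  mean_rho <- vapply(c(2, 4, 8, 16, 32), function(p) {
    d <- noisy_sample(p = p, seed = 21)
    rho <- withr::with_seed(77, vapply(seq_len(3000), function(i) {
      est <- random_estimate(d)
      suppressWarnings(cor(est$estimates, d$sample_means,
                           method = "spearman"))
    }, numeric(1)))
    mean(rho)
  }, numeric(1))
  expect_equal(mean_rho[1], 1)
  expect_true(all(diff(mean_rho) < 0))
  expect_lt(mean_rho[5], 0.2)
})
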