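test_that("AR(1) correlation matrix has the power structure", {
  expect_equal(ar1_correlation(0, 3), diag(3))
  C <- ar1_correlation(0.5, 3)
  expect_equal(C[1, 3], 0.25)
  expect_equal(diag(C), rep(1, 3))
  expect_equal(ar1_correlation(0.975, 2)[1, 2], 0.975)
  expect_error(ar1_correlation(1, 3), "gamma")
  expect_error(ar1_correlation(-0.1, 3), "gamma")
})

test_that("questionnaire times follow the jittered 6-month schedule", {
  set.seed(10)
  t1 <- sample_questionnaire_times(5000, K = 1)
  expect_true(all(t1 %in% c(4, 5, 6, 7, 8, 9)))   # 6*1 - 2 .. 6*1 + 3
  t10 <- sample_questionnaire_times(5000, K = 10)
  expect_true(all(t10 > 0))
  expect_true(all(t10[, 5] %in% (30 + (-2:3))))
  expect_error(sample_questionnaire_times(10, K = 11), "1..10")
})

test_that("jitter law frequencies pass a goodness-of-fit check", {
  set.seed(11)
  n <- 1e6
  t5 <- sample_questionnaire_times(n, K = 5)[, 5]
  counts <- table(factor(t5, levels = 30 + (-2:3)))
  p <- c(0.10, 0.15, 0.45, 0.15, 0.10, 0.05)
  gof <- suppressWarnings(chisq.test(counts, p = p))
  expect_gt(gof$p.value, 0.001)
  expect_equal(unname(counts[3] / n), 0.45, tolerance = 0.005)
})

test_that("copula thresholding calibrates the marginals at every gamma", {
  set.seed(12)
  for (g in c(0, 0.975)) {
    X <- sample_correlated_binary(1e5, ar1_correlation(g, 10), 0.2)
    # binomial 4-sigma band around 0.2 at n = 1e5
    expect_true(all(abs(colMeans(X) - 0.2) < 4 * sqrt(0.2 * 0.8 / 1e5)))
  }
})

test_that("joint exposure probability matches the orthant oracle", {
  set.seed(13)
  a <- qnorm(0.2)
  expect_equal(a, -0.8416212, tolerance = 1e-6)
  for (g in c(0.5, 0.975)) {
    X <- sample_correlated_binary(2e5, ar1_correlation(g, 2), 0.2)
    p11 <- mean(X[, 1] == 1 & X[, 2] == 1)
    oracle <- orthant_prob(a, g)
    expect_lt(abs(p11 - oracle), 4 * sqrt(oracle * (1 - oracle) / 2e5))
  }
})

test_that("trajectory persistence increases with the latent correlation", {
  set.seed(14)
  agree <- sapply(c(0, 0.5, 0.975, 0.9999), function(g) {
    X <- sample_correlated_binary(2e4, ar1_correlation(g, 10), 0.2)
    mean(X[, -1] == X[, -10])
  })
  expect_true(all(diff(agree) > 0))
  # near-perfect latent correlation: adjacent waves disagree on <1%
  expect_gt(agree[4], 0.99)
})

test_that("scenario effect curves match their definitions", {
  s1 <- dlm_scenario(1)
  expect_equal(true_effect(s1, c(6, 60)), c(0.15, 0.15))
  s3 <- dlm_scenario(3)
  expect_equal(true_effect(s3, 35.9), 0)
  expect_equal(true_effect(s3, 36), s3$params$s3_height)
  expect_equal(true_effect(s3, 47), s3$params$s3_height)
  expect_equal(true_effect(s3, 47.1), 0)
  s2 <- dlm_scenario(2)
  vertex <- s2$params$s2_vertex
  grid <- seq(4, 63, by = 0.5)
  expect_equal(grid[which.max(true_effect(s2, grid))], vertex)
  expect_error(dlm_scenario(4), "unknown scenario")
  expect_error(true_effect(s1, -1), "positive")
})

test_that("outcome generation matches closed-form logistic rates", {
  set.seed(15)
  n <- 2e5
  sc <- dlm_scenario(1)
  times <- sample_questionnaire_times(n, 10)
  zero <- matrix(0L, n, 10)
  y0 <- simulate_outcomes(zero, times, sc)
  expect_lt(abs(mean(y0) - plogis(-2.2)), 4 * sqrt(0.1 * 0.9 / n))
  all1 <- matrix(1L, n, 10)
  y1 <- simulate_outcomes(all1, times, sc)
  expect_lt(abs(mean(y1) - plogis(-0.7)),           # mu = -2.2 + 10 * 0.15
            4 * sqrt(0.33 * 0.67 / n))
})

test_that("scenario-1 prevalence matches the binomial-mixture oracle", {
  d <- simulate_dlm_data(dlm_scenario(1), gamma = 0, n = 1e5, seed = 16)
  oracle <- constant_effect_prevalence()
  expect_gt(oracle, 0.12)   # baseline near 10% plus the exposure load
  expect_lt(oracle, 0.14)
  expect_lt(abs(mean(d$y) - oracle), 4 * sqrt(oracle * (1 - oracle) / 1e5))
})

test_that("data sets are reproducible and uncorrelated when gamma is zero", {
  d1 <- simulate_dlm_data(dlm_scenario(2), gamma = 0.975, n = 2000, seed = 99)
  d2 <- simulate_dlm_data(dlm_scenario(2), gamma = 0.975, n = 2000, seed = 99)
  expect_identical(d1$exposures, d2$exposures)
  expect_identical(d1$times, d2$times)
  expect_identical(d1$y, d2$y)

  d0 <- simulate_dlm_data(dlm_scenario(1), gamma = 0, n = 1e5, seed = 20)
  cors <- cor(d0$exposures)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.011)
})

test_that("wide-format conversion lays out exposures and lags by wave", {
  d <- simulate_dlm_data(dlm_scenario(1), gamma = 0, n = 50, seed = 2)
  df <- as.data.frame(d)
  expect_equal(names(df),
               c("id", "y", paste0("x", 1:10), paste0("lag", 1:10)))
  expect_equal(df$x3, d$exposures[, 3])
  expect_equal(df$lag7, d$times[, 7])
})
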