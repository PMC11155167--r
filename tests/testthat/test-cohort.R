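test_that("cohort defaults hit the target outcome and exposure rates", {
  ch <- simulate_cohort(50000, seed = 31)
  expect_lt(abs(mean(ch$y) - 0.17), 0.01)
  prev <- colMeans(ch[c("x1", "x2", "x3")])
  expect_lt(max(abs(prev - c(0.125, 0.172, 0.143))), 0.01)
  expect_true(all(prev > 0.10 & prev < 0.20))
})

test_that("wave lags sit within three months of their modes", {
  ch <- simulate_cohort(20000, seed = 32)
  expect_true(all(abs(ch$lag1 - 18) <= 3))
  expect_true(all(abs(ch$lag2 - 30) <= 3))
  expect_true(all(abs(ch$lag3 - 39) <= 3))
  # the mode itself is the most common response time
  expect_equal(as.integer(names(which.max(table(ch$lag2)))), 30)
})

test_that("exposure is persistent across waves", {
  ch <- simulate_cohort(30000, seed = 33)
  X <- as.matrix(ch[c("x1", "x2", "x3")])
  expect_gt(cor(X[, 2], X[, 3]), 0.7)
  # among mid-pregnancy owners, most still own at 6 months
  expect_gt(mean(X[X[, 3] == 1, 2]), 0.75)
})

test_that("generation is reproducible and truth is recorded", {
  a <- simulate_cohort(2000, seed = 34, log_or = log(1.2))
  b <- simulate_cohort(2000, seed = 34, log_or = log(1.2))
  expect_identical(a, b)
  truth <- attr(a, "truth")
  expect_equal(truth$log_or, log(1.2))
  expect_equal(truth$lag_modes, c(18, 30, 39))
  expect_true(is.finite(truth$intercept))
})

cohort_formula <- y ~ child_sex + maternal_asthma + preterm + income + area

test_that("a basis-representable injected effect is covered by the DLM interval", {
  # constant lag effect = delta (log 1.15, 0, 0, 0): the model is correctly
  # specified, so the pointwise interval should cover the truth ~95% of the time
  covered <- vapply(1:10, function(s) {
    ch <- simulate_cohort(60000, seed = 400 + s,
                          effect = function(t) rep(log(1.15), length(t)))
    fit <- fpdlm(cohort_formula, ch, exposures = c("x1", "x2", "x3"),
                 lags = c("lag1", "lag2", "lag3"))
    eff <- lag_effects(fit, 32)
    eff$ci_low < 1.15 && 1.15 < eff$ci_high
  }, logical(1))
  expect_gte(sum(covered), 8)
})

test_that("a narrow indicator window is smoothed and attenuated by the basis", {
  # an effect confined to lags 31-34 is not representable by the smooth
  # basis: only the 6-month wave (realized lags 27-33) partly overlaps it,
  # so the fitted curve at lag 32 concentrates the wave-average effect,
  # well below the in-window truth (the misspecification bias by design)
  est <- vapply(1:5, function(s) {
    ch <- simulate_cohort(60000, seed = 500 + s, window = c(31, 34),
                          log_or = log(2))
    fit <- fpdlm(cohort_formula, ch, exposures = c("x1", "x2", "x3"),
                 lags = c("lag1", "lag2", "lag3"))
    lag_effects(fit, 32)$beta_hat
  }, numeric(1))
  expect_gt(mean(est), 0)            # the peak is still localized...
  expect_lt(mean(est), log(2))       # ...but attenuated below the truth
})

test_that("cohort arguments are validated", {
  expect_error(simulate_cohort(0), ">= 1")
  expect_error(simulate_cohort(10, prevalence = c(0.5, 1.2, 0.1)),
               "prevalence")
  expect_error(simulate_cohort(10, latent_cor = 1), "latent_cor")
})
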