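test_that("constraint coefficients are recovered from a constant-effect cohort", {
  # truth: beta(t) = 0.15 for all t, i.e. delta = (0.15, 0, 0, 0)
  d <- make_scenario1_data(n = 10000, gamma = 0.975, seed = 101)
  fit <- fpdlm_fit(d$y, d$exposures, d$times)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$cov_delta))
  expect_true(all(abs(fit$delta - c(0.15, 0, 0, 0)) < 3 * se))
})

test_that("degenerate exposure designs are refused with a diagnostic", {
  d <- make_scenario1_data(n = 500, seed = 3)
  zero <- matrix(0L, 500, 10)
  expect_error(fpdlm_fit(d$y, zero, d$times), "no information")

  # three shared lags cannot identify a four-term basis
  X3 <- d$exposures[, 1:3]
  expect_error(fpdlm_fit(d$y, X3, c(18, 30, 39)), "3 distinct lag")
})

test_that("constant-basis model reduces to exposure-count regression", {
  d <- make_scenario1_data(n = 5000, gamma = 0, seed = 11)
  fit <- fpdlm_fit(d$y, d$exposures, d$times, powers = 0)
  count_fit <- fit_logistic(cbind(1, rowSums(d$exposures)), d$y)
  expect_equal(unname(fit$delta), unname(count_fit$coefficients[2]),
               tolerance = 1e-8)
})

test_that("saturated basis with shared lags reproduces the Multi model", {
  set.seed(21)
  n <- 8000
  lags <- c(18, 30, 39)
  X <- sample_correlated_binary(n, ar1_correlation(0.5, 3), 0.2)
  y <- rbinom(n, 1, plogis(-2 + X %*% c(0.3, 0.1, -0.2)))
  dat <- data.frame(y = y, x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
  fit <- fpdlm_fit(y, X, lags, powers = c(0, 1, 2))
  multi <- fit_multi(y ~ 1, dat, exposures = c("x1", "x2", "x3"))
  eff <- lag_effects(fit, lags)
  expect_equal(eff$beta_hat, multi$beta_hat, tolerance = 1e-6)
  expect_equal(eff$se, multi$se, tolerance = 1e-6)
})

test_that("formula interface matches the matrix interface and predicts", {
  cohort <- simulate_cohort(4000, seed = 5, log_or = log(1.5))
  fit <- fpdlm(y ~ child_sex + maternal_asthma, cohort,
               exposures = c("x1", "x2", "x3"),
               lags = c("lag1", "lag2", "lag3"))
  Z <- model.matrix(~ child_sex + maternal_asthma, cohort)[, -1]
  fit2 <- fpdlm_fit(cohort$y, as.matrix(cohort[c("x1", "x2", "x3")]),
                    as.matrix(cohort[c("lag1", "lag2", "lag3")]), Z = Z)
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-10)

  p1 <- predict(fit, type = "response")
  p2 <- predict(fit, newdata = cohort, type = "response")
  expect_equal(unname(p1), unname(p2), tolerance = 1e-10)
  expect_equal(predict(fit, newdata = cohort, type = "link"),
               qlogis(p2), tolerance = 1e-8)
})

test_that("delta-method variance is non-negative across the grid", {
  d <- make_scenario1_data(n = 4000, gamma = 0.975, seed = 17)
  fit <- fpdlm_fit(d$y, d$exposures, d$times)
  eff <- lag_effects(fit, seq(4, 63, by = 0.5))
  expect_true(all(eff$se >= 0))
  expect_true(all(is.finite(eff$se)))
})

test_that("print, summary and residuals behave", {
  cohort <- simulate_cohort(2000, seed = 9)
  fit <- fpdlm(y ~ child_sex, cohort, exposures = c("x1", "x2", "x3"),
               lags = c("lag1", "lag2", "lag3"))
  expect_output(print(fit), "Fractional-polynomial distributed lag")
  expect_output(print(summary(fit)), "Coefficients")
  r <- residuals(fit, type = "pearson")
  expect_length(r, nrow(cohort))
  # pearson residual identity: sum of squares near n for a calibrated model
  expect_equal(mean(residuals(fit, type = "response")), 0, tolerance = 0.01)
})
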