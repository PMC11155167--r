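fake_study <- function(values, truth_const, models = "dlm", K = 10) {
  reps <- length(values)
  est <- array(rep(values, K * length(models)),
               dim = c(reps, K, length(models)),
               dimnames = list(NULL, 6 * seq_len(K), models))
  structure(list(estimates = est,
                 converged = matrix(TRUE, reps, length(models),
                                    dimnames = list(NULL, models)),
                 models = models, times = 6 * seq_len(K),
                 scenario = dlm_scenario(1, constant = truth_const),
                 gamma = 0, n = NA, reps = reps, seed = NA,
                 n_failed = stats::setNames(rep(0, length(models)), models)),
            class = "dlm_sim_study")
}

test_that("bias, EmpSE and MSE match hand computation", {
  perf <- compute_metrics(fake_study(c(0.1, 0.2, 0.3), truth_const = 0.2))
  row <- perf[perf$time == 6, ]
  expect_equal(row$bias_x100, 0, tolerance = 1e-12)
  expect_equal(row$empse_x100, 10)            # sd with n-1 denominator
  expect_equal(row$mse_x100, 100 * 0.02 / 3)  # mean of (0.01, 0, 0.01)
})

test_that("repeated identical estimates give zero EmpSE and MSE = bias^2", {
  perf <- compute_metrics(fake_study(c(0.25, 0.25), truth_const = 0.2))
  row <- perf[perf$time == 12, ]
  expect_equal(row$empse, 0)
  expect_equal(row$mse, row$bias^2, tolerance = 1e-15)
})

test_that("the three metrics are internally consistent on a real run", {
  st <- run_replications(dlm_scenario(1), gamma = 0, n = 2000, reps = 20,
                         seed = 7)
  perf <- compute_metrics(st)
  r <- perf$n_reps
  expect_true(all(abs(perf$mse - (perf$bias^2 + perf$empse^2 * (r - 1) / r))
                  < 1e-12))
  expect_true(all(perf$mse >= 0 & perf$empse >= 0))
})

test_that("replication runs are deterministic and sliceable", {
  st1 <- run_replications(dlm_scenario(1), gamma = 0, n = 1500, reps = 4,
                          seed = 3, models = "multi")
  st2 <- run_replications(dlm_scenario(1), gamma = 0, n = 1500, reps = 4,
                          seed = 3, models = "multi")
  expect_identical(st1$estimates, st2$estimates)

  # counter-based substreams: the first 2 reps of a 4-rep run ARE the 2-rep run
  st_small <- run_replications(dlm_scenario(1), gamma = 0, n = 1500,
                               reps = 2, seed = 3, models = "multi")
  expect_equal(head_replications(st1, 2)$estimates, st_small$estimates)
})

test_that("requested models determine the estimate layout", {
  st <- run_replications(dlm_scenario(1), gamma = 0, n = 1500, reps = 2,
                         seed = 5, models = c("single", "dlm"))
  expect_equal(dim(st$estimates), c(2, 10, 2))
  expect_equal(dimnames(st$estimates)[[3]], c("single", "dlm"))
  expect_named(st$n_failed, c("single", "dlm"))
})

test_that("metric tables are tidy, exact and round-trippable", {
  st <- run_replications(dlm_scenario(1), gamma = 0, n = 1500, reps = 3,
                         seed = 9)
  perf <- compute_metrics(st)
  dir <- withr::local_tempdir()
  paths <- write_metric_tables(perf, dir)
  expect_setequal(basename(paths), c("bias.csv", "empse.csv", "mse.csv"))
  bias <- read.csv(file.path(dir, "bias.csv"))
  expect_equal(nrow(bias), 10 * 3)          # 10 times x 3 models
  expect_equal(names(bias), c("scenario", "gamma", "time", "model",
                              "value_raw", "value_x100"))
  expect_equal(bias$value_raw,
               perf$bias[order(perf$scenario, perf$gamma, perf$time,
                               perf$model)],
               tolerance = 1e-15)
  expect_equal(bias$value_x100, 100 * bias$value_raw, tolerance = 1e-14)
})
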