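#' Run a replicated simulation study
#'
#' Repeats the generate–fit cycle: each replication draws a fresh data set
#' ([simulate_dlm_data()]) and fits the requested models, recording the
#' estimated exposure effect at the canonical questionnaire lags
#' 6, 12, ..., 6K months. For the Single and Multi models the estimate at
#' canonical lag 6k is the k-th exposure coefficient (those models index
#' exposures by questionnaire and ignore the per-subject jitter, exactly
#' as their model equations do); for the distributed lag model it is the
#' fitted curve evaluated at 6k.
#'
#' Per-replication seeds are derived deterministically from `seed` by a
#' counter scheme, so any single replication can be re-run in isolation
#' with [replication_seed()]. Replications whose fit fails or does not
#' converge are recorded as `NA`, counted, and excluded from the metrics;
#' they are never silently retried.
#'
#' @param scenario a [dlm_scenario()] object.
#' @param gamma AR(1) latent correlation used to generate the exposures.
#' @param n subjects per replication.
#' @param reps number of replications (>= 2).
#' @param models subset of `c("single", "multi", "dlm")`.
#' @param seed master seed.
#' @param powers basis powers for the distributed lag fits.
#' @return An object of class `"dlm_sim_study"`: estimates array
#'   (`reps` x `K` x `models`), convergence matrix, failure counts and the
#'   run configuration.
#' @examples
#' st <- run_replications(dlm_scenario(1), gamma = 0, n = 800, reps = 3,
#'                        seed = 1)
#' compute_metrics(st)[1:4, ]
#' @seealso [compute_metrics()], [write_metric_tables()]
#' @export
run_replications <- function(scenario, gamma, n = 10000, reps = 1000,
                             models = c("single", "multi", "dlm"),
                             seed = 1, powers = c(0, 1, 2, 0.5)) {
  stopifnot(inherits(scenario, "dlm_scenario"))
  models <- match.arg(models, several.ok = TRUE)
  if (reps < 2) stop("'reps' must be >= 2", call. = FALSE)
  K <- scenario$K
  canonical <- 6 * seq_len(K)
  est <- array(NA_real_, dim = c(reps, K, length(models)),
               dimnames = list(NULL, canonical, models))
  conv <- matrix(TRUE, reps, length(models), dimnames = list(NULL, models))
  for (r in seq_len(reps)) {
    dat <- simulate_dlm_data(scenario, gamma, n,
                             seed = replication_seed(seed, r))
    ones <- rep(1, n)
    for (m in seq_along(models)) {
      res <- tryCatch(switch(models[m],
        single = {
          b <- numeric(K)
          ok <- TRUE
          for (k in seq_len(K)) {
            f <- fit_logistic(cbind(ones, dat$exposures[, k]), dat$y)
            b[k] <- f$coefficients[2L]
            ok <- ok && f$converged
          }
          list(b = b, ok = ok)
        },
        multi = {
          f <- fit_logistic(cbind(ones, dat$exposures), dat$y)
          list(b = f$coefficients[1L + seq_len(K)], ok = f$converged)
        },
        dlm = {
          f <- fpdlm_fit(dat$y, dat$exposures, dat$times, powers = powers)
          list(b = lag_effects(f, canonical)$beta_hat, ok = f$converged)
        }), error = function(e) list(b = rep(NA_real_, K), ok = FALSE))
      est[r, , m] <- res$b
      conv[r, m] <- res$ok
    }
  }
  n_failed <- colSums(!conv)
  if (any(n_failed > 0.01 * reps)) {
    warning("more than 1% of replications failed for model(s): ",
            paste(models[n_failed > 0.01 * reps], collapse = ", "),
            call. = FALSE)
  }
  structure(list(estimates = est, converged = conv, models = models,
                 times = canonical, scenario = scenario, gamma = gamma,
                 n = n, reps = reps, seed = seed, powers = powers,
                 n_failed = n_failed),
            class = "dlm_sim_study")
}

#' Deterministic per-replication seed
#'
#' Counter-based derivation of the seed for replication `r` under master
#' seed `master`; lets a single replication of [run_replications()] be
#' reproduced in isolation via [simulate_dlm_data()].
#'
#' @param master master seed (integer).
#' @param r replication index (1-based).
#' @return An integer seed below 2^31.
#' @export
replication_seed <- function(master, r) {
  ## multiplicative mix kept in double precision (< 2^53), reduced mod 2^31-1
  as.integer(((as.double(master) %% 2147483647) * 48271 + r * 30269) %%
               2147483647)
}

#' @export
print.dlm_sim_study <- function(x, ...) {
  cat(sprintf(paste0("Simulation study: scenario %d, gamma = %g, n = %d, ",
                     "%d replications\nmodels: %s; failures: %s\n"),
              x$scenario$id, x$gamma, x$n, x$reps,
              paste(x$models, collapse = ", "),
              paste(x$n_failed, collapse = ", ")))
  invisible(x)
}

#' Bias, empirical SE and MSE of the replicated estimates
#'
#' For each model and canonical lag, computes across converged
#' replications: bias = mean estimate minus the true effect at the
#' canonical lag, EmpSE = sample standard deviation of the estimates
#' (n - 1 denominator), and MSE = mean squared deviation from the truth.
#' Values are returned on the raw log-odds scale together with the
#' conventional x100 reporting scale.
#'
#' @param study a `"dlm_sim_study"` from [run_replications()], optionally
#'   with its estimates truncated to fewer replications.
#' @return A data frame of class `"dlm_perf"` with columns `scenario`,
#'   `gamma`, `time`, `model`, `bias`, `empse`, `mse`, `bias_x100`,
#'   `empse_x100`, `mse_x100`, `n_reps`; the per-model failure counts are
#'   kept in `attr(, "n_failed")`.
#' @export
compute_metrics <- function(study) {
  stopifnot(inherits(study, "dlm_sim_study"))
  truth <- true_effect(study$scenario, study$times)
  rows <- list()
  for (m in seq_along(study$models)) {
    keep <- study$converged[, m] & !apply(is.na(study$estimates[, , m,
                                                                drop = FALSE]),
                                          1, any)
    if (sum(keep) < 2) {
      stop("fewer than 2 converged replications for model '",
           study$models[m], "'", call. = FALSE)
    }
    E <- study$estimates[keep, , m, drop = TRUE]
    for (k in seq_along(study$times)) {
      v <- E[, k]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = study$scenario$id, gamma = study$gamma,
        time = study$times[k], model = study$models[m],
        bias = mean(v) - truth[k],
        empse = stats::sd(v),
        mse = mean((v - truth[k])^2),
        n_reps = sum(keep))
    }
  }
  out <- do.call(rbind, rows)
  out$bias_x100 <- 100 * out$bias
  out$empse_x100 <- 100 * out$empse
  out$mse_x100 <- 100 * out$mse
  out <- out[order(out$scenario, out$gamma, out$time, out$model), ]
  rownames(out) <- NULL
  attr(out, "n_failed") <- study$n_failed
  class(out) <- c("dlm_perf", "data.frame")
  out
}

#' Truncate a simulation study to its first replications
#'
#' Because per-replication seeds are counter-based, the first `reps`
#' replications of a larger run are exactly the run that `reps`
#' replications would have produced; this helper slices them out, e.g. to
#' report metrics at a reduced replication count from one set of fits.
#'
#' @param study a `"dlm_sim_study"`.
#' @param reps number of leading replications to keep.
#' @return A `"dlm_sim_study"` with `reps` replications.
#' @export
head_replications <- function(study, reps) {
  stopifnot(inherits(study, "dlm_sim_study"), reps >= 2,
            reps <= study$reps)
  study$estimates <- study$estimates[seq_len(reps), , , drop = FALSE]
  study$converged <- study$converged[seq_len(reps), , drop = FALSE]
  study$reps <- reps
  study$n_failed <- colSums(!study$converged)
  study
}

#' Write the performance tables to tidy CSV files
#'
#' Emits `bias.csv`, `empse.csv` and `mse.csv` under `dir`, each tidy with
#' columns `scenario, gamma, time, model, value_raw, value_x100` in a
#' deterministic row order. Values are printed with 17 significant digits
#' so a CSV round trip reproduces them exactly.
#'
#' @param perf a `"dlm_perf"` data frame from [compute_metrics()], or a
#'   row-bound collection of them.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths of the three files.
#' @export
write_metric_tables <- function(perf, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  perf <- perf[order(perf$scenario, perf$gamma, perf$time, perf$model), ]
  paths <- character(3)
  metrics <- c("bias", "empse", "mse")
  for (i in seq_along(metrics)) {
    m <- metrics[i]
    tidy <- data.frame(scenario = perf$scenario, gamma = perf$gamma,
                       time = perf$time, model = perf$model,
                       value_raw = sprintf("%.17g", perf[[m]]),
                       value_x100 = sprintf("%.17g", 100 * perf[[m]]))
    paths[i] <- file.path(dir, paste0(m, ".csv"))
    utils::write.csv(tidy, paths[i], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
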