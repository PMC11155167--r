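#' Lag-effect curve with delta-method Wald intervals
#'
#' Reconstructs the exposure effect at given lags from a fitted
#' distributed lag model. At lag t the log odds ratio is
#' \eqn{\hat\beta(t) = T(t)^\top \hat\delta} with
#' \eqn{T(t)} the basis vector (default \eqn{(1, t, t^2, \sqrt t)}), and
#' its variance is the delta-method quadratic form
#' \eqn{V(\hat\beta(t)) = T(t)^\top \mathrm{Cov}(\hat\delta)\, T(t)}.
#' Pointwise Wald confidence intervals are reported on the odds-ratio
#' scale; a lag is flagged significant when the interval excludes 1
#' (two-sided level `1 - conf_level`).
#'
#' @param object a fitted [fpdlm()] model.
#' @param lags lags (months) at which to evaluate the curve; defaults to
#'   the fit's integer grid spanning the observed lag range. Order is
#'   preserved.
#' @param conf_level confidence level for the Wald intervals (default 0.95,
#'   i.e. z = 1.959964).
#' @return A data frame of class `"lag_effects"` with one row per lag and
#'   columns `lag`, `beta_hat`, `se`, `or`, `ci_low`, `ci_high`,
#'   `significant`.
#' @examples
#' cohort <- simulate_cohort(4000, seed = 7, log_or = log(1.4))
#' fit <- fpdlm(y ~ 1, cohort, exposures = c("x1", "x2", "x3"),
#'              lags = c("lag1", "lag2", "lag3"))
#' lag_effects(fit, lags = c(18, 24, 30, 36))
#' @export
lag_effects <- function(object, lags = object$grid, conf_level = 0.95) {
  stopifnot(inherits(object, "fpdlm"))
  if (!object$converged) {
    stop("model fit did not converge; lag effects are not reported ",
         "from a non-converged fit", call. = FALSE)
  }
  if (!is.numeric(conf_level) || conf_level < 0 || conf_level > 1) {
    stop("'conf_level' must be in [0, 1]", call. = FALSE)
  }
  if (length(lags) == 0L) {
    out <- data.frame(lag = numeric(0), beta_hat = numeric(0),
                      se = numeric(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      significant = logical(0))
    class(out) <- c("lag_effects", "data.frame")
    attr(out, "conf_level") <- conf_level
    return(out)
  }
  B <- fp_basis(lags, object$powers)
  beta <- drop(B %*% object$delta)
  v <- rowSums((B %*% object$cov_delta) * B)
  ## the covariance is PSD up to rounding; clip sub-epsilon negatives
  v[v < 0 & v > -1e-10 * max(abs(v), 1)] <- 0
  if (any(v < 0) || any(!is.finite(beta)) || any(!is.finite(v))) {
    stop("non-finite or negative variance in the lag-effect curve",
         call. = FALSE)
  }
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(lag = lags,
                    beta_hat = beta,
                    se = se,
                    or = exp(beta),
                    ci_low = exp(beta - z * se),
                    ci_high = exp(beta + z * se),
                    significant = abs(beta) > z * se & se >= 0)
  class(out) <- c("lag_effects", "data.frame")
  attr(out, "conf_level") <- conf_level
  rownames(out) <- NULL
  out
}

#' Critical exposure windows
#'
#' Scans the lag-effect curve on a sorted grid and returns the maximal runs
#' of consecutive grid points whose odds ratio is statistically significant
#' (pointwise two-sided Wald test). Each run is reported as a closed lag
#' interval `[from, to]`.
#'
#' The tests are pointwise: no multiplicity adjustment is applied across
#' the grid, matching the usual reading of distributed-lag effect curves.
#'
#' @param x a `"lag_effects"` data frame or a fitted `"fpdlm"` model.
#' @param ... for the `fpdlm` method, `lags` and `conf_level` passed on to
#'   [lag_effects()].
#' @return A data frame with columns `from`, `to` (lag months) and
#'   `n_points`; zero rows when nothing is significant.
#' @examples
#' eff <- data.frame(lag = 28:33, beta_hat = 0, se = 1, or = 1,
#'                   ci_low = 0, ci_high = 2,
#'                   significant = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
#' class(eff) <- c("lag_effects", "data.frame")
#' critical_windows(eff)   # one window: lags 30 to 32
#' @export
critical_windows <- function(x, ...) UseMethod("critical_windows")

#' @rdname critical_windows
#' @export
critical_windows.fpdlm <- function(x, ...) {
  critical_windows(lag_effects(x, ...))
}

#' @rdname critical_windows
#' @export
critical_windows.lag_effects <- function(x, ...) {
  if (nrow(x) == 0L) {
    return(data.frame(from = numeric(0), to = numeric(0),
                      n_points = integer(0)))
  }
  if (is.unsorted(x$lag, strictly = TRUE)) {
    stop("lag-effect grid must be strictly increasing to define windows",
         call. = FALSE)
  }
  r <- rle(x$significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(from = x$lag[starts[keep]],
             to = x$lag[ends[keep]],
             n_points = r$lengths[keep])
}
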