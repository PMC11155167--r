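#' Per-time-point logistic fits (Single model)
#'
#' The simplest analysis of a time-varying binary exposure: one adjusted
#' logistic regression per time point, each containing only that time
#' point's exposure indicator (plus covariates). With strongly correlated
#' exposure histories each separate coefficient absorbs the effects of the
#' other time points, so the Single model is biased away from the null
#' under high exposure persistence.
#'
#' @param formula outcome-and-covariates formula, e.g. `y ~ sex`; use
#'   `y ~ 1` for no covariates.
#' @param data data frame with the outcome, covariates and exposure
#'   columns.
#' @param exposures character vector naming the K 0/1 exposure columns, or
#'   an n x K matrix.
#' @param lags optional: lag columns (or matrix/vector) used only to label
#'   each time point by its modal lag; when absent, time points are
#'   labelled 1..K.
#' @param conf_level Wald confidence level.
#' @return A data frame of class `"lag_fits"`, one row per time point, with
#'   columns `model`, `time`, `beta_hat`, `se`, `or`, `ci_low`, `ci_high`,
#'   `significant`, `converged`.
#' @examples
#' cohort <- simulate_cohort(4000, seed = 11, log_or = log(1.3))
#' fit_single(y ~ child_sex, cohort, exposures = c("x1", "x2", "x3"),
#'            lags = c("lag1", "lag2", "lag3"))
#' @seealso [fit_multi()], [fpdlm()]
#' @export
fit_single <- function(formula, data, exposures, lags = NULL,
                       conf_level = 0.95) {
  parts <- comparator_parts(formula, data, exposures, lags)
  K <- ncol(parts$X)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    design <- cbind("(Intercept)" = 1, exposure = parts$X[, k], parts$Z)
    f <- fit_logistic(design, parts$y)
    rows[[k]] <- lag_fit_row("single", parts$times[k],
                             f$coefficients[2L], sqrt(f$cov[2L, 2L]),
                             f$converged, conf_level)
  }
  finish_lag_fits(do.call(rbind, rows))
}

#' Simultaneous logistic fit (Multi model)
#'
#' All K exposure indicators entered together in a single adjusted
#' logistic regression. Unbiased on average for the per-time-point effects,
#' but the near-collinearity of highly persistent exposures inflates the
#' coefficient variances — the motivation for constraining the lag profile
#' with a distributed lag model.
#'
#' @inheritParams fit_single
#' @return A data frame of class `"lag_fits"`, as in [fit_single()], with
#'   `model = "multi"`.
#' @export
fit_multi <- function(formula, data, exposures, lags = NULL,
                      conf_level = 0.95) {
  parts <- comparator_parts(formula, data, exposures, lags)
  K <- ncol(parts$X)
  design <- cbind("(Intercept)" = 1, parts$X, parts$Z)
  cn <- design_condition(design)
  if (!is.finite(cn) || cn > 1e10) {
    stop("exposure columns are perfectly collinear; the simultaneous ",
         "(Multi) model is not estimable", call. = FALSE)
  }
  f <- fit_logistic(design, parts$y)
  idx <- 1L + seq_len(K)
  rows <- lapply(seq_len(K), function(k) {
    lag_fit_row("multi", parts$times[k], f$coefficients[idx[k]],
                sqrt(f$cov[idx[k], idx[k]]), f$converged, conf_level)
  })
  finish_lag_fits(do.call(rbind, rows))
}

## shared front end: outcome, encoded covariates, exposure matrix, labels
comparator_parts <- function(formula, data, exposures, lags) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y) - 1
  Zfull <- stats::model.matrix(attr(mf, "terms"), mf)
  Z <- Zfull[, setdiff(colnames(Zfull), "(Intercept)"), drop = FALSE]
  X <- resolve_matrix(data, exposures, "exposures")
  storage.mode(X) <- "double"
  if (any(X != 0 & X != 1)) {
    stop("'exposures' must be 0/1 indicators", call. = FALSE)
  }
  times <- if (is.null(lags)) {
    seq_len(ncol(X))
  } else {
    L <- resolve_matrix(data, lags, "lags", allow_vector = TRUE)
    if (is.null(dim(L))) L <- matrix(L, nrow(X), ncol(X), byrow = TRUE)
    apply(L, 2, modal_value)
  }
  list(y = y, X = X, Z = Z, times = times)
}

modal_value <- function(v) {
  tb <- table(v)
  as.numeric(names(tb)[which.max(tb)])
}

lag_fit_row <- function(model, time, beta, se, converged, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(model = model, time = time, beta_hat = beta, se = se,
             or = exp(beta),
             ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
             significant = is.finite(se) & abs(beta) > z * se,
             converged = converged)
}

finish_lag_fits <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("lag_fits", "data.frame")
  df
}

#' @export
print.lag_fits <- function(x, digits = 4, ...) {
  cat(sprintf("Per-time-point exposure effects (%s model)\n",
              paste(unique(x$model), collapse = "/")))
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}
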