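#' Fit a fractional-polynomial distributed lag logistic model
#'
#' `fpdlm()` fits a logistic regression in which the effects of a binary
#' exposure recorded at K past time points enter jointly, with the per-lag
#' log odds ratio constrained to a fractional polynomial of the lag
#' (default \eqn{\beta(t) = \delta_0 + \delta_1 t + \delta_2 t^2 +
#' \delta_3\sqrt t}). The constraint collapses the K exposure indicators
#' into `length(powers)` regressors (see [collapse_exposures()]), so the
#' model is estimated by ordinary maximum likelihood:
#' \deqn{\mathrm{logit}\, \pi_i = \beta_0 + \delta^\top W_i + \eta^\top Z_i.}
#'
#' This is the standard remedy for the multicollinearity that makes the
#' simultaneous ("Multi") model unstable when repeated exposures are highly
#' correlated: the smooth constraint borrows strength across adjacent lags
#' while still letting the effect vary over time. The fitted lag-effect
#' curve \eqn{\hat\beta(t) = T(t)^\top\hat\delta} and its delta-method
#' variance \eqn{T(t)^\top \mathrm{Cov}(\hat\delta)\, T(t)} are obtained
#' with [lag_effects()]; contiguous significant stretches of the curve are
#' the estimated critical windows ([critical_windows()]).
#'
#' @section Identifiability:
#' A p-term basis needs at least p distinct lag values across subjects;
#' with exactly 3 shared lags the default 4-term basis is unidentifiable.
#' In questionnaire cohorts it is the per-subject variation in response
#' times (lags jittered around each wave's target age) that makes the full
#' basis estimable. The fit refuses, with a diagnostic naming the number of
#' distinct lags, when the condition number of the design exceeds
#' `cond_tol`.
#'
#' @param formula model formula for the outcome and baseline covariates,
#'   e.g. `y ~ sex + maternal_asthma`; use `y ~ 1` for no covariates.
#'   Categorical covariates are dummy (reference-cell) encoded with the
#'   first factor level as reference.
#' @param data data frame containing the outcome, covariates and (when
#'   `exposures`/`lags` are column names) the exposure history.
#' @param exposures either a character vector naming the K 0/1 exposure
#'   columns of `data` (e.g. `c("x1","x2","x3")`), or an n x K 0/1 matrix.
#' @param lags either a character vector naming the matching lag columns
#'   (months before the outcome assessment), or an n x K positive matrix,
#'   or a length-K vector of shared lags.
#' @param powers fractional-polynomial powers of the lag constraint;
#'   default `c(0, 1, 2, 0.5)`.
#' @param cond_tol condition-number threshold above which the design is
#'   declared unidentifiable.
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap,
#'   passed to [fit_logistic()].
#' @return An object of class `"fpdlm"`: a list with components including
#'   `coefficients` (intercept, basis and covariate terms), `delta`,
#'   `eta`, `cov` (full covariance), `cov_delta`, `converged`, `n`, `K`,
#'   `powers`, `lag_range` and `grid` (default integer evaluation grid,
#'   observed minimum to maximum lag).
#' @examples
#' cohort <- simulate_cohort(4000, seed = 42, log_or = log(1.3))
#' fit <- fpdlm(y ~ child_sex + maternal_asthma, cohort,
#'              exposures = c("x1", "x2", "x3"),
#'              lags = c("lag1", "lag2", "lag3"))
#' summary(fit)
#' head(lag_effects(fit))
#' @references The constrained-lag formulation and delta-method inference
#'   follow the standard distributed-lag literature for time-varying
#'   exposures in epidemiology.
#' @seealso [lag_effects()], [critical_windows()], [fit_single()],
#'   [fit_multi()]
#' @export
fpdlm <- function(formula, data, exposures, lags,
                  powers = c(0, 1, 2, 0.5), cond_tol = 1e10,
                  epsilon = 1e-10, maxit = 100L) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  if (nrow(mf) != nrow(data)) {
    stop("missing values in outcome or covariates; ",
         "the model expects complete cases", call. = FALSE)
  }
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y) - 1
  Zfull <- stats::model.matrix(attr(mf, "terms"), mf)
  Z <- Zfull[, setdiff(colnames(Zfull), "(Intercept)"), drop = FALSE]
  X <- resolve_matrix(data, exposures, "exposures")
  L <- resolve_matrix(data, lags, "lags", allow_vector = TRUE)
  fit <- fpdlm_fit(y, X, L, Z = Z, powers = powers, cond_tol = cond_tol,
                   epsilon = epsilon, maxit = maxit)
  fit$call <- cl
  fit$formula <- formula
  if (is.character(exposures)) fit$exposure_cols <- exposures
  if (is.character(lags)) fit$lag_cols <- lags
  fit
}

## Pull a subject-by-wave matrix out of `data` by column name, or pass a
## matrix/vector through unchanged.
resolve_matrix <- function(data, what, label, allow_vector = FALSE) {
  if (is.character(what)) {
    missing_cols <- setdiff(what, names(data))
    if (length(missing_cols)) {
      stop("column(s) not found in 'data' for '", label, "': ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    as.matrix(data[what])
  } else if (is.matrix(what) || is.data.frame(what)) {
    as.matrix(what)
  } else if (allow_vector && is.numeric(what)) {
    what
  } else {
    stop("'", label, "' must be column names or a numeric matrix",
         call. = FALSE)
  }
}

#' Matrix-interface workhorse for the distributed lag fit
#'
#' Lower-level counterpart of [fpdlm()] in the `glm`/`glm.fit` tradition:
#' takes the outcome, exposure and lag matrices (and an optional
#' already-encoded covariate matrix) directly, with no formula machinery.
#' Used by the simulation engine where thousands of fits are run.
#'
#' @param y 0/1 outcome vector.
#' @param exposures n x K 0/1 matrix.
#' @param lags n x K positive matrix, or length-K vector of shared lags.
#' @param Z optional numeric covariate matrix (already dummy-encoded),
#'   without an intercept column.
#' @inheritParams fpdlm
#' @return An object of class `"fpdlm"`; see [fpdlm()].
#' @export
fpdlm_fit <- function(y, exposures, lags, Z = NULL,
                      powers = c(0, 1, 2, 0.5), cond_tol = 1e10,
                      epsilon = 1e-10, maxit = 100L) {
  W <- collapse_exposures(exposures, lags, powers)
  if (all(W == 0)) {
    stop("all exposure indicators are zero: the collapsed design W carries ",
         "no information and the lag effect is not estimable", call. = FALSE)
  }
  n <- length(y)
  if (is.null(Z)) {
    Z <- matrix(numeric(0), n, 0)
  } else {
    Z <- as.matrix(Z)
    storage.mode(Z) <- "double"
  }
  X <- cbind("(Intercept)" = rep(1, n), W, Z)
  cn <- design_condition(X)
  if (!is.finite(cn) || cn > cond_tol) {
    L <- if (is.null(dim(lags))) lags else as.matrix(lags)
    n_distinct <- length(unique(as.vector(L)))
    stop(sprintf(paste0(
      "design including the collapsed exposure columns is numerically ",
      "collinear (condition number %.3g > %.3g). Only %d distinct lag ",
      "value(s) are present for a %d-term fractional-polynomial basis; at ",
      "least %d distinct lags are required (per-subject jitter in response ",
      "times usually provides them). Consider fewer basis terms via ",
      "'powers'."), cn, cond_tol, n_distinct, ncol(W), ncol(W)),
      call. = FALSE)
  }
  fit <- fit_logistic(X, y, epsilon = epsilon, maxit = maxit)
  idx <- 1L + seq_len(ncol(W))
  delta <- fit$coefficients[idx]
  names(delta) <- colnames(W)
  eta <- fit$coefficients[-c(1L, idx)]
  Lmat <- if (is.null(dim(lags))) {
    matrix(lags, n, length(lags), byrow = TRUE)
  } else as.matrix(lags)
  lag_range <- range(Lmat)
  grid <- seq(ceiling(lag_range[1]), floor(lag_range[2]))
  structure(list(
    coefficients = fit$coefficients,
    delta = delta,
    eta = eta,
    cov = fit$cov,
    cov_delta = fit$cov[idx, idx, drop = FALSE],
    converged = fit$converged,
    separated = fit$separated,
    iter = fit$iter,
    n = n,
    K = ncol(as.matrix(exposures)),
    powers = powers,
    lag_range = lag_range,
    grid = grid,
    condition_number = cn,
    deviance = fit$deviance,
    null.deviance = fit$null.deviance,
    df.residual = fit$df.residual,
    fitted.values = fit$fitted.values,
    linear.predictors = qlogis_safe(fit$fitted.values),
    y = fit$y,
    call = match.call()
  ), class = "fpdlm")
}

qlogis_safe <- function(p) {
  p <- pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
  stats::qlogis(p)
}
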