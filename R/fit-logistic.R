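#' Logistic maximum-likelihood fit on a prepared design matrix
#'
#' Shared estimation engine for the distributed lag model and its
#' comparators: a binomial GLM fitted by iteratively reweighted least
#' squares (via [stats::glm.fit()]) with a tight convergence tolerance, plus
#' the coefficient covariance from the inverse Fisher information at the
#' optimum. The caller supplies the complete design matrix, including the
#' intercept column.
#'
#' Non-convergence, rank deficiency and (quasi-)complete separation are
#' reported through the `converged` flag and its companion fields rather
#' than silently returning an estimate.
#'
#' @param x numeric design matrix, one row per subject, intercept included
#'   by the caller.
#' @param y 0/1 outcome vector of length `nrow(x)`.
#' @param epsilon relative deviance convergence tolerance for IRLS.
#' @param maxit maximum number of IRLS iterations.
#' @return A list with components `coefficients`, `cov` (inverse-information
#'   covariance, `NA` rows/columns for aliased coefficients), `converged`,
#'   `iter`, `rank`, `aliased`, `separated`, `deviance`, `null.deviance`,
#'   `df.residual`, `fitted.values` and `y`.
#' @examples
#' set.seed(1)
#' x <- cbind(1, rbinom(500, 1, 0.4))
#' y <- rbinom(500, 1, plogis(-1 + 0.8 * x[, 2]))
#' fit_logistic(x, y)$coefficients
#' @export
fit_logistic <- function(x, y, epsilon = 1e-10, maxit = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) {
    stop("'x' has ", nrow(x), " rows but 'y' has length ", length(y),
         call. = FALSE)
  }
  if (any(!is.finite(y)) || any(y != 0 & y != 1)) {
    stop("'y' must be a 0/1 outcome vector", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = epsilon,
                                                maxit = maxit))
  )
  p <- ncol(x)
  coefs <- fit$coefficients
  aliased <- is.na(coefs)
  rank <- fit$rank
  cov <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  if (rank > 0L) {
    R <- qr.R(fit$qr)[seq_len(rank), seq_len(rank), drop = FALSE]
    piv <- fit$qr$pivot[seq_len(rank)]
    cov[piv, piv] <- chol2inv(R)
  }
  mu <- fit$fitted.values
  ## (quasi-)separation: fitted probabilities pinned at the numerical 0/1
  ## boundary; moderate tail probabilities are legitimate and not flagged
  separated <- any(mu < 1e-12 | mu > 1 - 1e-12)
  converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    !any(aliased) && !separated
  list(coefficients = coefs,
       cov = cov,
       converged = converged,
       iter = fit$iter,
       rank = rank,
       aliased = aliased,
       separated = separated,
       deviance = fit$deviance,
       null.deviance = fit$null.deviance,
       df.residual = fit$df.residual,
       fitted.values = mu,
       y = y)
}

## Condition number of a design matrix (ratio of extreme singular values).
## Returns Inf for numerically singular designs.
design_condition <- function(x) {
  d <- svd(x, nu = 0, nv = 0)$d
  if (min(d) <= 0) return(Inf)
  max(d) / min(d)
}
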