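#' Fractional-polynomial lag basis
#'
#' Evaluates the fractional-polynomial basis of the exposure lag at one or
#' more lags. The default powers `c(0, 1, 2, 0.5)` give the four-term basis
#' \eqn{(1, t, t^2, \sqrt{t})} used to constrain the per-time-point log odds
#' ratios \eqn{\beta(t)} of a distributed lag model to a smooth function of
#' lag:
#' \deqn{\beta(t) = \delta_0 + \delta_1 t + \delta_2 t^2 + \delta_3 \sqrt{t}.}
#'
#' Lags are measured in months before the outcome assessment and must be
#' strictly positive (the outcome time is lag 0, and fractional powers of
#' non-positive lags are undefined).
#'
#' @param t numeric vector of lags in months; strictly positive and finite.
#' @param powers numeric vector of distinct fractional-polynomial powers.
#'   A power of 0 denotes the constant term.
#' @return A `length(t)` by `length(powers)` numeric matrix, one column per
#'   basis term, with descriptive column names such as `"w(sqrt(t))"`.
#' @examples
#' fp_basis(c(18, 30, 39))
#' fp_basis(4)          # (1, 4, 16, 2)
#' fp_basis(36, powers = c(0, 1, 2))
#' @seealso [collapse_exposures()], [fpdlm()]
#' @export
fp_basis <- function(t, powers = c(0, 1, 2, 0.5)) {
  if (!is.numeric(t) || length(t) == 0L) {
    stop("'t' must be a non-empty numeric vector of lags", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("lags must be finite and strictly positive (months before outcome)",
         call. = FALSE)
  }
  if (!is.numeric(powers) || length(powers) == 0L ||
      anyDuplicated(powers) || any(!is.finite(powers))) {
    stop("'powers' must be distinct finite numeric exponents", call. = FALSE)
  }
  out <- vapply(powers, function(p) t^p, numeric(length(t)))
  matrix(out, nrow = length(t),
         dimnames = list(NULL, basis_names(powers)))
}

## human-readable column labels for the basis terms
basis_names <- function(powers) {
  vapply(powers, function(p) {
    if (p == 0) "w(1)"
    else if (p == 0.5) "w(sqrt(t))"
    else if (p == 1) "w(t)"
    else sprintf("w(t^%g)", p)
  }, character(1))
}

#' Collapse an exposure history onto the lag basis
#'
#' Converts a subject-by-time-point binary exposure matrix and the matching
#' per-subject lags into the low-dimensional collapsed design
#' \deqn{W_{ij} = \sum_k b_j(t_{ik}) X_{ik},}
#' where \eqn{b_j} is the j-th basis term. Substituting the
#' fractional-polynomial constraint into the simultaneous logistic model
#' turns the K exposure indicators into these `length(powers)` regressors,
#' so the constrained distributed lag model is an ordinary logistic
#' regression on `W`.
#'
#' The first (constant-basis) column of `W` is the subject's count of
#' exposed time points; a subject with no exposure contributes an all-zero
#' row.
#'
#' @param exposures n x K matrix (or data frame) of 0/1 exposure indicators,
#'   one column per questionnaire/time point.
#' @param lags n x K matrix of positive lags in months, aligned with
#'   `exposures`; a length-K vector is recycled across subjects (all
#'   subjects observed at the same lags).
#' @param powers fractional-polynomial powers, as in [fp_basis()].
#' @return n x `length(powers)` numeric matrix `W`.
#' @examples
#' X <- rbind(c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
#' collapse_exposures(X, lags = c(18, 30, 39))
#' @export
collapse_exposures <- function(exposures, lags, powers = c(0, 1, 2, 0.5)) {
  X <- as.matrix(exposures)
  storage.mode(X) <- "double"
  if (any(!is.finite(X)) || any(X != 0 & X != 1)) {
    stop("'exposures' must be a matrix of 0/1 indicators", call. = FALSE)
  }
  n <- nrow(X)
  K <- ncol(X)
  if (is.null(dim(lags))) {
    if (length(lags) != K) {
      stop("'lags' has length ", length(lags), " but there are ", K,
           " exposure columns", call. = FALSE)
    }
    L <- matrix(lags, n, K, byrow = TRUE)
  } else {
    L <- as.matrix(lags)
    storage.mode(L) <- "double"
    if (!all(dim(L) == dim(X))) {
      stop("'lags' must have the same dimensions as 'exposures'",
           call. = FALSE)
    }
  }
  if (any(!is.finite(L)) || any(L <= 0)) {
    stop("lags must be finite and strictly positive", call. = FALSE)
  }
  W <- matrix(0, n, length(powers),
              dimnames = list(NULL, basis_names(powers)))
  for (k in seq_len(K)) {
    W <- W + fp_basis(L[, k], powers) * X[, k]
  }
  W
}
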