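#' @export
print.fpdlm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Fractional-polynomial distributed lag logistic model\n")
  if (!is.null(x$call)) {
    cat("Call: ", paste(deparse(x$call), collapse = "\n"), "\n", sep = "")
  }
  cat(sprintf("n = %d subjects, K = %d exposure time points, basis powers: %s\n",
              x$n, x$K, paste(format(x$powers), collapse = ", ")))
  cat(sprintf("observed lag range: %.1f to %.1f months\n",
              x$lag_range[1], x$lag_range[2]))
  if (!x$converged) {
    cat("WARNING: fit did not converge",
        if (isTRUE(x$separated)) " (separation suspected)", "\n", sep = "")
  }
  cat("\nConstraint coefficients (delta):\n")
  print.default(format(x$delta, digits = digits), print.gap = 2,
                quote = FALSE)
  invisible(x)
}

#' Summarise a fitted distributed lag model
#'
#' Coefficient table (estimate, standard error, Wald z and p-value) for the
#' intercept, the basis-constraint coefficients delta and any covariate
#' coefficients, together with deviance information.
#'
#' @param object a fitted `"fpdlm"` model.
#' @param ... unused.
#' @return An object of class `"summary.fpdlm"`.
#' @export
summary.fpdlm <- function(object, ...) {
  est <- object$coefficients
  se <- sqrt(diag(object$cov))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(call = object$call, coefficients = tab,
                 deviance = object$deviance,
                 null.deviance = object$null.deviance,
                 df.residual = object$df.residual,
                 n = object$n, K = object$K, powers = object$powers,
                 converged = object$converged, iter = object$iter,
                 condition_number = object$condition_number),
            class = "summary.fpdlm")
}

#' @export
print.summary.fpdlm <- function(x,
                                digits = max(3L, getOption("digits") - 3L),
                                ...) {
  if (!is.null(x$call)) {
    cat("Call: ", paste(deparse(x$call), collapse = "\n"), "\n\n", sep = "")
  }
  cat(sprintf("Distributed lag logistic fit: n = %d, K = %d, %d basis terms\n",
              x$n, x$K, length(x$powers)))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits, ...)
  cat(sprintf("\nNull deviance: %.1f;  Residual deviance: %.1f on %d df\n",
              x$null.deviance, x$deviance, x$df.residual))
  cat(sprintf("IRLS iterations: %d;  design condition number: %.3g\n",
              x$iter, x$condition_number))
  invisible(x)
}

#' @export
coef.fpdlm <- function(object, ...) object$coefficients

#' @export
vcov.fpdlm <- function(object, ...) object$cov

#' Predictions from a fitted distributed lag model
#'
#' Computes the linear predictor or outcome probability for the fitting
#' data or for new subjects. New data must be a data frame containing the
#' same covariate, exposure and lag columns used in the [fpdlm()] call
#' (column-name interface only).
#'
#' @param object a fitted `"fpdlm"` model.
#' @param newdata optional data frame of new subjects.
#' @param type `"link"` for the log-odds or `"response"` for the
#'   probability scale.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.fpdlm <- function(object, newdata = NULL,
                          type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    if (is.null(object$exposure_cols) || is.null(object$formula)) {
      stop("prediction on new data requires a model fitted through the ",
           "formula interface with named exposure/lag columns",
           call. = FALSE)
    }
    tt <- stats::delete.response(stats::terms(object$formula))
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.omit)
    Zfull <- stats::model.matrix(tt, mf)
    Z <- Zfull[, setdiff(colnames(Zfull), "(Intercept)"), drop = FALSE]
    W <- collapse_exposures(as.matrix(newdata[object$exposure_cols]),
                            as.matrix(newdata[object$lag_cols]),
                            object$powers)
    X <- cbind(1, W, Z)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.fpdlm <- function(object,
                            type = c("deviance", "pearson", "response"),
                            ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted.values
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) *
           sqrt(-2 * (y * log(pmax(mu, .Machine$double.xmin)) +
                        (1 - y) * log(pmax(1 - mu, .Machine$double.xmin)))))
}

#' Plot the odds-ratio lag curve of a distributed lag fit
#'
#' Draws the fitted odds ratio against lag with a shaded pointwise Wald
#' confidence band; grid points inside a detected critical window are
#' marked. The horizontal reference line is OR = 1.
#'
#' @param x a fitted `"fpdlm"` model.
#' @param lags evaluation grid, defaulting to the fit's integer lag grid.
#' @param conf_level Wald confidence level.
#' @param ... further arguments passed to [graphics::plot.default()].
#' @return Invisibly, the `"lag_effects"` data frame that was plotted.
#' @export
plot.fpdlm <- function(x, lags = x$grid, conf_level = 0.95, ...) {
  eff <- lag_effects(x, lags = lags, conf_level = conf_level)
  ylim <- range(eff$ci_low, eff$ci_high, 1)
  graphics::plot.default(eff$lag, eff$or, type = "n", ylim = ylim,
                         xlab = "lag (months before outcome)",
                         ylab = "odds ratio", ...)
  graphics::polygon(c(eff$lag, rev(eff$lag)),
                    c(eff$ci_low, rev(eff$ci_high)),
                    border = NA, col = grDevices::adjustcolor("grey40", 0.25))
  graphics::abline(h = 1, lty = 2)
  graphics::lines(eff$lag, eff$or, lwd = 2)
  if (any(eff$significant)) {
    graphics::points(eff$lag[eff$significant], eff$or[eff$significant],
                     pch = 16)
  }
  invisible(eff)
}

#' @export
print.lag_effects <- function(x, digits = 4, ...) {
  cat(sprintf("Lag-effect curve (%d lags, %.0f%% pointwise Wald intervals)\n",
              nrow(x), 100 * (attr(x, "conf_level") %||% 0.95)))
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
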