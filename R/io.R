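#' Read a wide-format cohort CSV
#'
#' Reads the cohort dialect used throughout the package: comma-separated,
#' header mandatory, one row per subject with columns `id`, `y` (0/1),
#' `x1..xK` (0/1 exposure indicators), `lag1..lagK` (positive months
#' before the outcome assessment) and any further columns treated as
#' categorical covariates. Covariates become factors whose reference level
#' is the first category encountered in file order.
#'
#' @param path CSV file path.
#' @return A data frame with attributes `K`, `exposure_cols`, `lag_cols`
#'   and `covariate_cols`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("id", "y")) {
    if (!col %in% names(df)) {
      stop("cohort file is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  lcols <- grep("^lag[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  lcols <- lcols[order(as.integer(sub("^lag", "", lcols)))]
  if (length(xcols) == 0L) {
    stop("no exposure columns (x1, x2, ...) found", call. = FALSE)
  }
  if (length(xcols) != length(lcols)) {
    stop("found ", length(xcols), " exposure column(s) but ",
         length(lcols), " lag column(s); they must pair up", call. = FALSE)
  }
  if (any(df$y != 0 & df$y != 1)) {
    stop("outcome column 'y' must be 0/1", call. = FALSE)
  }
  for (cx in xcols) {
    if (any(df[[cx]] != 0 & df[[cx]] != 1)) {
      stop("exposure column '", cx, "' contains non-binary values",
           call. = FALSE)
    }
  }
  for (cl in lcols) {
    if (any(!is.finite(df[[cl]])) || any(df[[cl]] <= 0)) {
      stop("lag column '", cl, "' must be strictly positive months",
           call. = FALSE)
    }
  }
  covcols <- setdiff(names(df), c("id", "y", xcols, lcols))
  for (cc in covcols) {
    if (is.character(df[[cc]])) {
      df[[cc]] <- factor(df[[cc]], levels = unique(df[[cc]]))
    }
  }
  attr(df, "K") <- length(xcols)
  attr(df, "exposure_cols") <- xcols
  attr(df, "lag_cols") <- lcols
  attr(df, "covariate_cols") <- covcols
  df
}

#' Write a cohort data frame to CSV
#'
#' Inverse of [read_cohort()]: plain comma-separated output with header,
#' `.` decimal separator and no row names.
#'
#' @param cohort data frame in the wide cohort layout.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a lag-effect curve to CSV
#'
#' Columns `lag, beta_hat, se, or, ci_low, ci_high, significant`, one row
#' per grid point.
#'
#' @param effects a `"lag_effects"` data frame from [lag_effects()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_effects <- function(effects, path) {
  cols <- c("lag", "beta_hat", "se", "or", "ci_low", "ci_high",
            "significant")
  utils::write.csv(as.data.frame(effects)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
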