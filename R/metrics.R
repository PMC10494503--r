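#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken as estimated minus measured, so overestimation gives
#' positive bias. Limits of agreement are bias +/- 1.96 x SD of the
#' differences, with the sample (n - 1) standard deviation and no small-sample
#' correction.
#'
#' @param estimated,measured Equal-length numeric vectors, pg/mL; `measured`
#'   must be strictly positive and length >= 2.
#' @return Named list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @examples
#' bland_altman(c(5.1, 4.0, 6.2), c(5.0, 4.4, 5.9))
#' @export
bland_altman <- function(estimated, measured) {
  if (length(estimated) != length(measured)) {
    stop("estimated and measured must have equal length", call. = FALSE)
  }
  if (length(estimated) < 2L) {
    stop("Bland-Altman analysis needs at least 2 pairs", call. = FALSE)
  }
  if (any(!is.finite(measured)) || any(measured <= 0)) {
    stop("measured values must be finite and strictly positive", call. = FALSE)
  }
  d <- estimated - measured
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Proportion of estimates within a relative fraction of the measurement
#'
#' P15 and P30 are `p_within()` at fractions 0.15 and 0.30: the proportion of
#' pairs whose absolute error is at most the stated fraction of the measured
#' value. Ties at the boundary count as within.
#'
#' @param estimated,measured Equal-length numeric vectors; `measured` strictly
#'   positive.
#' @param fraction Positive relative tolerance (0.15 for P15).
#' @return Proportion in `[0, 1]`.
#' @examples
#' p_within(c(1.2, 1.0, 2.0), c(1.0, 1.0, 1.0), 0.30)
#' @export
p_within <- function(estimated, measured, fraction) {
  if (length(estimated) != length(measured) || length(estimated) < 1L) {
    stop("estimated and measured must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(measured)) || any(measured <= 0)) {
    stop("measured values must be finite and strictly positive", call. = FALSE)
  }
  stopifnot(is.numeric(fraction), length(fraction) == 1L, fraction > 0)
  mean(abs(estimated - measured) / measured <= fraction)
}

#' Root mean square error
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @examples
#' rmse(c(1, 2), c(2, 4))
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1L) {
    stop("predicted and observed must be non-empty and of equal length",
         call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' Adjusted coefficient of determination
#'
#' `R2 = 1 - SSR/SST`; adjusted for `p` predictors as
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`. Categorical blocks count each
#' indicator column as a predictor.
#'
#' @param observed Response values with nonzero variance.
#' @param fitted Fitted values from the model.
#' @param n_predictors Number of predictor columns in the model (excluding the
#'   intercept).
#' @return Adjusted R-squared.
#' @examples
#' adjusted_r2(c(1, 2, 3), c(1.14, 1.79, 3.07), 1)
#' @export
adjusted_r2 <- function(observed, fitted, n_predictors) {
  n <- length(observed)
  if (length(fitted) != n) {
    stop("observed and fitted must have equal length", call. = FALSE)
  }
  if (n <= n_predictors + 1L) {
    stop("need n > n_predictors + 1 for the adjusted R-squared", call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("observed values have zero variance", call. = FALSE)
  r2 <- 1 - sum((observed - fitted)^2) / sst
  1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
}

#' Agreement and accuracy report for estimated vs measured free 25(OH)D
#'
#' One row per subgroup plus an `"overall"` row, each carrying n, Bland-Altman
#' bias and 95% limits of agreement, P15, P30 and RMSE. Subgroups with fewer
#' than 2 pairs are flagged `incomplete` (bias/LOA need at least 2) instead of
#' failing.
#'
#' @param estimated,measured Equal-length numeric vectors, pg/mL.
#' @param subgroups Optional vector of subgroup labels, same length.
#' @return Data frame of class `free25d_validation` with columns `subgroup`,
#'   `n`, `bias`, `loa_low`, `loa_high`, `p15`, `p30`, `rmse`, `incomplete`.
#' @examples
#' validate_estimates(c(5.1, 4.0, 6.2, 5.4), c(5.0, 4.4, 5.9, 5.2),
#'                    subgroups = c("a", "a", "b", "b"))
#' @export
validate_estimates <- function(estimated, measured, subgroups = NULL) {
  if (length(estimated) < 1L) stop("empty estimate series", call. = FALSE)
  if (length(estimated) != length(measured)) {
    stop("estimated and measured must have equal length", call. = FALSE)
  }
  one <- function(est, mea, label) {
    n <- length(est)
    incomplete <- n < 2L
    ba <- if (incomplete) list(bias = NA_real_, loa_low = NA_real_,
                               loa_high = NA_real_)
          else bland_altman(est, mea)
    data.frame(
      subgroup = label, n = n, bias = ba$bias, loa_low = ba$loa_low,
      loa_high = ba$loa_high,
      p15 = p_within(est, mea, 0.15), p30 = p_within(est, mea, 0.30),
      rmse = rmse(est, mea), incomplete = incomplete,
      stringsAsFactors = FALSE
    )
  }
  out <- one(as.numeric(estimated), as.numeric(measured), "overall")
  if (!is.null(subgroups)) {
    stopifnot(length(subgroups) == length(estimated))
    for (g in unique(as.character(subgroups))) {
      idx <- which(as.character(subgroups) == g)
      out <- rbind(out, one(as.numeric(estimated)[idx],
                            as.numeric(measured)[idx], g))
    }
  }
  class(out) <- c("free25d_validation", "data.frame")
  out
}

#' @export
print.free25d_validation <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$p15 <- sprintf("%.0f%%", 100 * y$p15)
  y$p30 <- sprintf("%.0f%%", 100 * y$p30)
  for (col in c("bias", "loa_low", "loa_high", "rmse")) {
    y[[col]] <- round(y[[col]], digits)
  }
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
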