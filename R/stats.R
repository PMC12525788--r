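#' Standard error of calibration (SEC)
#'
#' Root mean square of the training residuals with degrees of freedom
#' `n - n_factors - 1` (one lost to centering, one per latent factor).
#'
#' @param residuals numeric vector of fitted minus reference values.
#' @param n_factors number of latent factors in the model.
#' @return SEC in the units of the reference (mg g-1).
#' @export
sec <- function(residuals, n_factors) {
  n <- length(residuals)
  dof <- n - n_factors - 1
  if (dof <= 0)
    stop("non-positive degrees of freedom (n = ", n, ", factors = ",
         n_factors, ")", call. = FALSE)
  sqrt(sum(residuals^2) / dof)
}

#' Bias and bias-corrected standard error of prediction (SEP)
#'
#' The bias is the mean prediction error; the SEP is computed after
#' removing it: `sqrt(sum((e - bias)^2) / (n - 1))`.
#'
#' @param errors numeric vector of predicted minus reference values.
#' @return list with `bias` and `sep` (both mg g-1).
#' @export
sep_bias_corrected <- function(errors) {
  n <- length(errors)
  if (n < 2) stop("need at least 2 errors", call. = FALSE)
  bias <- mean(errors)
  list(bias = bias, sep = sqrt(sum((errors - bias)^2) / (n - 1)))
}

#' One minus variance ratio (cross-validation R-squared analogue)
#'
#' `1 - Var(reference - predictions) / Var(reference)` with the population
#' variance convention (divide by n), floored at 0 for reporting.
#'
#' @param predictions cross-validation predictions.
#' @param reference aligned reference values.
#' @return unitless value in [0, 1].
#' @export
one_minus_variance_ratio <- function(predictions, reference) {
  if (length(predictions) != length(reference) || length(reference) < 2)
    stop("need aligned vectors of length >= 2", call. = FALSE)
  vr <- var_pop(reference)
  if (vr <= 0) stop("constant reference values", call. = FALSE)
  max(0, 1 - var_pop(reference - predictions) / vr)
}

var_pop <- function(x) mean((x - mean(x))^2)

#' Squared Pearson correlation between predictions and reference
#'
#' @param predicted predicted values.
#' @param reference aligned reference values.
#' @return unitless value in [0, 1].
#' @export
r_squared <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(reference) < 3)
    stop("need aligned vectors of length >= 3", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(reference) == 0)
    stop("constant input", call. = FALSE)
  stats::cor(predicted, reference)^2
}

#' Summarize a calibration, cross-validation, or validation
#'
#' Builds an evaluation report with the statistic matching `kind`:
#' SEC (with the factor-count degrees-of-freedom correction) for
#' `"calibration"`, SECV as the root mean square of the pooled
#' cross-validation residuals (paired with the one-minus-variance-ratio)
#' for `"cross-validation"`, and bias-corrected SEP for `"validation"`.
#'
#' @param reference reference analyte values (mg g-1).
#' @param predicted aligned predicted/fitted values.
#' @param kind one of `"calibration"`, `"cross-validation"`, `"validation"`.
#' @param n_factors required for `kind = "calibration"`.
#' @param year optional label carried into the report.
#' @return object of class `evaluation_report` with fields `kind`, `year`,
#'   `n`, `mean`, `range`, `se`, `r2`, `bias`, `slope`.
#' @export
summarize_evaluation <- function(reference, predicted,
                                 kind = c("calibration", "cross-validation",
                                          "validation"),
                                 n_factors = NULL, year = NA) {
  kind <- match.arg(kind)
  if (length(reference) != length(predicted))
    stop("reference and predicted are not aligned", call. = FALSE)
  e <- predicted - reference
  if (kind == "calibration") {
    if (is.null(n_factors))
      stop("n_factors is required for a calibration report", call. = FALSE)
    se <- sec(e, n_factors)
    r2 <- r_squared(predicted, reference)
    bias <- mean(e)
  } else if (kind == "cross-validation") {
    if (!is.null(n_factors) && length(e) <= n_factors + 1)
      stop("too few samples for the factor count", call. = FALSE)
    se <- sqrt(mean(e^2))
    r2 <- one_minus_variance_ratio(predicted, reference)
    bias <- mean(e)
  } else {
    bc <- sep_bias_corrected(e)
    se <- bc$sep
    bias <- bc$bias
    r2 <- r_squared(predicted, reference)
  }
  slope <- if (stats::sd(predicted) > 0)
    stats::cov(reference, predicted) / stats::var(predicted) else NA_real_
  structure(list(kind = kind, year = year, n = length(reference),
                 mean = mean(reference),
                 range = c(min(reference), max(reference)),
                 se = se, r2 = r2, bias = bias, slope = slope),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s [%s]: n=%d, mean %.2f, range %.2f-%.2f, SE %.3f, R2 %.3f, bias %+.3f\n",
              x$kind, as.character(x$year), x$n, x$mean, x$range[1],
              x$range[2], x$se, x$r2, x$bias))
  invisible(x)
}

#' Render evaluation reports as a table
#'
#' @param reports a list of `evaluation_report` objects.
#' @return data.frame with columns Type, Year, n, Mean, Range, SE, R2.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r)
    data.frame(Type = r$kind, Year = as.character(r$year), n = r$n,
               Mean = round(r$mean, 2),
               Range = sprintf("%.2f-%.2f", r$range[1], r$range[2]),
               SE = round(r$se, 2), R2 = round(r$r2, 2),
               stringsAsFactors = FALSE)))
}
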