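# Evaluation metrics: R2, Willmott's degree of agreement, RMSE, RMSRE, and
# their averages Ag (goodness) and Ae (error). Reference values are the
# FAO-56 Penman-Monteith ET0; predictions come from a fitted model.

check_metric_inputs <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop("reference and predicted lengths differ", call. = FALSE)
  }
  if (length(reference) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (!all(is.finite(reference)) || !all(is.finite(predicted))) {
    stop("non-finite values in metric inputs", call. = FALSE)
  }
  invisible(NULL)
}

#' Coefficient of determination
#'
#' The standard `R2 = 1 - SSres / SStot`, with the total sum of squares
#' about the reference mean: 1 for a perfect prediction, 0 for the
#' reference-mean null model. A historical variant that rates a model by
#' `SSres / sum((ref - mean(pred))^2)` is available behind
#' `printed_form = TRUE` for auditing published tables; note it returns 0,
#' not 1, for a perfect prediction and is not used anywhere else in the
#' package.
#'
#' @param reference Reference ET0 values (mm per day).
#' @param predicted Model estimates, same length.
#' @param printed_form Use the historical ratio form (default `FALSE`).
#' @return R2, or `NA` when the reference is constant.
#' @export
coefficient_of_determination <- function(reference, predicted,
                                         printed_form = FALSE) {
  check_metric_inputs(reference, predicted)
  ss_res <- sum((reference - predicted)^2)
  if (printed_form) {
    denom <- sum((reference - mean(predicted))^2)
    if (denom == 0) return(NA_real_)
    return(ss_res / denom)
  }
  ss_tot <- sum((reference - mean(reference))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

#' Willmott's degree of agreement
#'
#' `d = 1 - sum((pred - ref)^2) / sum((|pred - mean(ref)| +
#' |ref - mean(ref)|)^2)`, bounded in [0, 1]; 1 for perfect agreement.
#'
#' @inheritParams coefficient_of_determination
#' @return d, or `NA` when the denominator is zero (both series constant at
#'   the reference mean).
#' @export
degree_of_agreement <- function(reference, predicted) {
  check_metric_inputs(reference, predicted)
  ref_mean <- mean(reference)
  denom <- sum((abs(predicted - ref_mean) + abs(reference - ref_mean))^2)
  if (denom == 0) return(NA_real_)
  1 - sum((predicted - reference)^2) / denom
}

#' Root mean square error
#' @inheritParams coefficient_of_determination
#' @return RMSE in mm per day; 0 iff perfect.
#' @export
rmse <- function(reference, predicted) {
  check_metric_inputs(reference, predicted)
  sqrt(mean((reference - predicted)^2))
}

#' Root mean square relative error
#'
#' RMSE of the errors scaled by the reference values; dimensionless. Any
#' zero reference value makes the estimator undefined and yields `NA`
#' (daily ET0 in the target climate is strictly positive, so this guards a
#' synthetic edge case, not a field case).
#'
#' @inheritParams coefficient_of_determination
#' @return RMSRE, or `NA` if any reference value is zero.
#' @export
rmsre <- function(reference, predicted) {
  check_metric_inputs(reference, predicted)
  if (any(reference == 0)) return(NA_real_)
  sqrt(mean(((reference - predicted) / reference)^2))
}

#' Combine component metrics into a report
#'
#' Average goodness `Ag = (R2 + d) / 2` and average error
#' `Ae = (RMSE + RMSRE) / 2` (mixed units: mm per day averaged with a
#' ratio, as defined). `NA` components propagate.
#'
#' @param r2,d,rmse,rmsre Component metric values.
#' @return An object of class `metric_report` (named list with `r2`, `d`,
#'   `rmse`, `rmsre`, `ag`, `ae`).
#' @export
combine_metrics <- function(r2, d, rmse, rmsre) {
  structure(list(r2 = r2, d = d, rmse = rmse, rmsre = rmsre,
                 ag = (r2 + d) / 2, ae = (rmse + rmsre) / 2),
            class = "metric_report")
}

#' Full metric report for one prediction series
#'
#' @inheritParams coefficient_of_determination
#' @return A `metric_report`.
#' @examples
#' metric_report(c(1, 2, 3), c(1, 2, 4))
#' @export
metric_report <- function(reference, predicted) {
  combine_metrics(
    r2 = coefficient_of_determination(reference, predicted),
    d = degree_of_agreement(reference, predicted),
    rmse = rmse(reference, predicted),
    rmsre = rmsre(reference, predicted)
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> R2=%.3f d=%.3f RMSE=%.3f RMSRE=%.3f Ag=%.3f Ae=%.3f\n",
    x$r2, x$d, x$rmse, x$rmsre, x$ag, x$ae))
  invisible(x)
}
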