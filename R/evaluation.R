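#' Signed per-stride errors
#'
#' Differences between estimated and reference stride lengths in
#' centimeters; the sign is kept so over- and underestimation can be split
#' downstream (an exact zero counts as underestimation so the two shares
#' always total 100%).
#'
#' @param est estimated stride lengths, m.
#' @param ref reference stride lengths, m.
#' @return numeric vector of signed errors, cm.
#' @export
stride_errors <- function(est, ref) {
  if (length(est) != length(ref))
    stopf("length mismatch: %d estimates vs %d references",
          length(est), length(ref))
  if (!length(est)) stopf("need at least one stride")
  (est - ref) * 100
}

mae_sd_cv <- function(abs_e) {
  n <- length(abs_e)
  mae <- mean(abs_e)
  sd_ <- if (n >= 2L) stats::sd(abs_e) else NA_real_
  cv <- if (is.na(sd_)) NA_real_ else if (mae > 0) sd_ / mae else 0
  c(MAE = mae, SD = sd_, CV = cv, n = n)
}

#' Error summary (MAE, SD, CV, over/under split)
#'
#' Summarizes signed errors the way the field's report tables do: MAE is
#' the mean absolute error, SD the sample standard deviation of the
#' absolute errors, and CV = SD / MAE.  The same three statistics are also
#' computed within the overestimated (`e > 0`) and underestimated
#' (`e <= 0`) subsets, along with their percentage shares.
#'
#' @param errors signed errors (cm for per-stride evaluation, % for
#'   walked-distance evaluation), length >= 1.
#' @param scope free-form label (model / position / speed).
#' @param units unit label carried into printing (`"cm"` or `"%"`).
#' @return object of class `eval_report`.
#' @export
error_summary <- function(errors, scope = "", units = "cm") {
  if (!length(errors)) stopf("need at least one error")
  assert_finite(errors, "errors")
  over <- errors > 0
  out <- list(scope = scope, units = units,
              overall = mae_sd_cv(abs(errors)),
              over = if (any(over)) mae_sd_cv(errors[over]) else NULL,
              under = if (any(!over)) mae_sd_cv(-errors[!over]) else NULL,
              over_share = 100 * mean(over),
              under_share = 100 * mean(!over),
              errors = errors)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(s) {
    if (is.null(s)) return("            --")
    sprintf("MAE %5.2f %s  SD %s  CV %s  (n=%d)", s[["MAE"]], x$units,
            if (is.na(s[["SD"]])) "  n/a" else sprintf("%5.2f", s[["SD"]]),
            if (is.na(s[["CV"]])) " n/a" else
              sprintf("%4.2f", round_half_up(s[["CV"]], 2L)),
            as.integer(s[["n"]]))
  }
  cat(sprintf("Evaluation%s\n",
              if (nzchar(x$scope)) paste0(" [", x$scope, "]") else ""))
  cat("  overall: ", fmt(x$overall), "\n", sep = "")
  cat("  over:    ", fmt(x$over),
      sprintf("  share %.2f%%", x$over_share), "\n", sep = "")
  cat("  under:   ", fmt(x$under),
      sprintf("  share %.2f%%", x$under_share), "\n", sep = "")
  invisible(x)
}

#' Walked-distance error
#'
#' Signed relative error of an estimated walked distance,
#' `e = (d_est - d) / d * 100`, in percent.
#'
#' @param d_est estimated walked distance, m.
#' @param d measured walked distance, m (> 0).
#' @return signed error in percent (vectorized).
#' @export
distance_error <- function(d_est, d) {
  if (any(d <= 0)) stopf("measured walked distance must be > 0")
  (d_est - d) / d * 100
}

#' Summary of per-trial walked-distance errors
#'
#' @param e signed per-trial distance errors in percent
#'   (from [distance_error]).
#' @param scope free-form label.
#' @return an [error_summary] report in percent units.
#' @export
polygon_summary <- function(e, scope = "") {
  error_summary(e, scope = scope, units = "%")
}

#' Coefficient of variation of an error table row
#'
#' `CV = SD / MAE`, rounded half-up to 2 decimals as printed in report
#' tables.  Exposed so published (MAE, SD) pairs can be checked directly.
#'
#' @param mae mean absolute error.
#' @param sd standard deviation of absolute errors.
#' @param digits decimals for display rounding (`NULL` for unrounded).
#' @return CV value(s).
#' @export
cv_from_mae_sd <- function(mae, sd, digits = 2L) {
  if (any(mae <= 0)) stopf("MAE must be > 0 to form a CV")
  cv <- sd / mae
  if (is.null(digits)) cv else round_half_up(cv, digits)
}
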