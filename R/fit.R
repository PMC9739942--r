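#' Fit a step-length model by least squares
#'
#' Calibrates the tunable constants of one registered model against
#' reference stride lengths, mirroring the field protocol: constants are
#' fitted per trial and sensor position on the first minutes of a
#' recording, then frozen for evaluation.
#'
#' @details Closed forms / linear fits per model:
#' \itemize{
#'   \item single-constant models (`base`, `mikov`, `bylemans`):
#'     `K = sum(d_ref * x) / sum(x^2)` with `x` the model's per-stride
#'     basis value — the exact least-squares solution through the origin.
#'   \item `proposed`: ordinary least squares on regressors
#'     `(F, a_r^0.1)` with no intercept (the model has none).
#'   \item `shin_park`: ordinary least squares on `(F, a_v, 1)`.
#'   \item `sharp_yu`: ordinary least squares in log space,
#'     `log d = c + K3 log(a_max - a_min) + K4 log F`.  Within one subject
#'     the height is constant, so `K1` and `h^K2` are not separately
#'     identifiable; the fit sets `K2 = 1` and `K1 = exp(c) / h`, which
#'     preserves predictions exactly.  The minimized objective for this
#'     model is the log-space residual sum of squares.
#' }
#'
#' @param model_id model identifier, see [sl_models].
#' @param strides data frame of stride features with a finite `d_ref`
#'   column (reference stride lengths, m), e.g. a `stride_table` joined
#'   with heel-marker references.  At least `max(5, n_constants + 2)` rows.
#' @param subject a [subject_profile]; required for the height-based model.
#' @param context calibration scope label stored in the result.
#' @param bylemans_variant see [sl_estimate].
#' @return object of class `sl_fit` with components `params`
#'   ([model_params]), `n`, `rss` (residual sum of squares of the fitted
#'   objective), `objective` (`"length"` or `"log_length"`), `fitted`,
#'   `residuals`, plus the training features.
#' @examples
#' f <- data.frame(F = c(0.9, 1.0, 1.1, 0.95, 1.05),
#'                 a_r = c(5, 6, 7, 5.5, 6.5))
#' f$d_ref <- 0.35 * f$F + 0.2 * f$a_r^0.1
#' fit <- sl_fit("proposed", f)
#' coef(fit)
#' @export
sl_fit <- function(model_id, strides, subject = NULL, context = "",
                   bylemans_variant = c("canonical", "inverse_root")) {
  model_id <- match.arg(model_id, MODEL_IDS)
  bylemans_variant <- match.arg(bylemans_variant)
  if (!"d_ref" %in% names(strides))
    stopf("strides must carry a d_ref column of reference lengths")
  strides <- strides[is.finite(strides$d_ref), , drop = FALSE]
  n <- nrow(strides)
  p <- length(MODEL_CONSTANTS[[model_id]])
  if (n < max(5L, p + 2L))
    stopf("model '%s' needs at least %d strides with reference lengths, got %d",
          model_id, max(5L, p + 2L), n)
  d <- strides$d_ref
  objective <- "length"

  if (model_id %in% c("base", "mikov", "bylemans")) {
    x <- switch(model_id,
      base = strides$a_r^0.1,
      mikov = (strides$a_max - strides$a_min)^0.25 / strides$F,
      bylemans = if (bylemans_variant == "canonical")
        0.1 * strides$a_mean * (strides$a_max - strides$a_min)^(1 / 2.7) /
          strides$F
      else
        0.1 * strides$a_mean * (strides$F *
          (strides$a_max - strides$a_min))^(-1 / 2.7))
    if (sum(x^2) == 0) stopf("degenerate basis: all basis values are zero")
    K <- sum(d * x) / sum(x^2)
    params <- model_params(model_id, c(K = K), context)
  } else if (model_id %in% c("proposed", "shin_park")) {
    X <- if (model_id == "proposed")
      cbind(F = strides$F, ar01 = strides$a_r^0.1)
    else
      cbind(F = strides$F, a_v = strides$a_v, intercept = rep(1, n))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stopf("rank-deficient design for model '%s': collinear regressor(s) %s",
            model_id, paste(dep, collapse = ", "))
    }
    beta <- qr.coef(qrX, d)
    params <- if (model_id == "proposed")
      model_params("proposed", c(K1 = beta[[1L]], K2 = beta[[2L]]), context)
    else
      model_params("shin_park",
                   c(K1 = beta[[1L]], K2 = beta[[2L]], K3 = beta[[3L]]),
                   context)
  } else { # sharp_yu
    if (is.null(subject))
      stopf("the height-based model needs a subject_profile")
    rng <- strides$a_max - strides$a_min
    if (any(d <= 0) || any(rng <= 0))
      stopf("log-space fit requires positive reference lengths and positive acceleration ranges")
    X <- cbind(intercept = rep(1, n), log_ar = log(rng), log_F = log(strides$F))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stopf("rank-deficient design for model 'sharp_yu': collinear regressor(s) %s",
            paste(dep, collapse = ", "))
    }
    beta <- qr.coef(qrX, log(d))
    params <- model_params("sharp_yu",
                           c(K1 = exp(beta[[1L]]) / subject$height, K2 = 1,
                             K3 = beta[[2L]], K4 = beta[[3L]]), context)
    objective <- "log_length"
  }

  fitted <- sl_estimate(strides, params, subject = subject,
                        bylemans_variant = bylemans_variant)
  res <- d - fitted
  rss <- if (objective == "length") sum(res^2)
         else sum((log(d) - log(fitted))^2)
  structure(list(params = params, n = n, rss = rss, objective = objective,
                 fitted = fitted, residuals = res, data = strides,
                 subject = subject, bylemans_variant = bylemans_variant),
            class = "sl_fit")
}

#' @export
print.sl_fit <- function(x, ...) {
  cat(sprintf("Step-length model fit ('%s', n = %d strides)\n",
              x$params$model_id, x$n))
  print(x$params)
  cat(sprintf("RSS (%s objective): %.6g;  MAE on training strides: %.2f cm\n",
              x$objective, x$rss, 100 * mean(abs(x$residuals))))
  invisible(x)
}

#' @export
coef.sl_fit <- function(object, ...) object$params$constants

#' @export
fitted.sl_fit <- function(object, ...) object$fitted

#' @export
residuals.sl_fit <- function(object, ...) object$residuals

#' @export
summary.sl_fit <- function(object, ...) {
  out <- list(params = object$params, n = object$n, rss = object$rss,
              objective = object$objective,
              mae_cm = 100 * mean(abs(object$residuals)),
              sd_cm = if (object$n > 1)
                100 * stats::sd(abs(object$residuals)) else NA_real_)
  class(out) <- "summary.sl_fit"
  out
}

#' @export
print.summary.sl_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("n = %d, RSS = %.6g (%s), training MAE = %.2f cm, SD = %.2f cm\n",
              x$n, x$rss, x$objective, x$mae_cm, x$sd_cm))
  invisible(x)
}

#' @export
predict.sl_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  sl_estimate(newdata, object$params, subject = object$subject,
              bylemans_variant = object$bylemans_variant)
}

#' Tune/evaluate split of a stride table
#'
#' Splits strides by time into a tuning window (first `tune_seconds` of the
#' trial, default 300 s = 5 min) and an evaluation window (the remainder),
#' the standard calibration protocol for ~15-min recordings.
#'
#' @param strides stride table with `start_idx`/`end_idx` or a `t_start`
#'   column; alternatively supply `t` giving each stride's start time.
#' @param t per-stride start times, seconds from trial start; derived from
#'   `t_start` when omitted.
#' @param tune_seconds length of the tuning window, seconds.
#' @return list with elements `tune` and `eval`, both stride tables.
#' @export
calibration_split <- function(strides, t = NULL, tune_seconds = 300) {
  if (is.null(t)) {
    if (!"t_start" %in% names(strides))
      stopf("supply per-stride start times via t or a t_start column")
    t <- strides$t_start
  }
  if (length(t) != nrow(strides))
    stopf("t must have one entry per stride")
  rel <- t - t[1L]
  list(tune = strides[rel < tune_seconds, , drop = FALSE],
       eval = strides[rel >= tune_seconds, , drop = FALSE])
}

#' Per-walking-speed calibration profiles
#'
#' Fits the adaptive (frequency + magnitude-range) model on each speed's
#' tuning strides and stores, alongside the constants, the mean stride
#' frequency and mean acceleration-magnitude range of those strides — the
#' input averages the adaptive selector matches against.
#'
#' @param trials named list: one stride table (tune-window strides with
#'   `d_ref`) per speed label, e.g. `list(slow = ..., normal = ...)`.
#' @param subject a [subject_profile].
#' @return object of class `speed_profiles`: a list of profiles, each with
#'   `speed_label`, `params`, `mean_F`, `mean_a_r`, `n`.
#' @export
fit_speed_profiles <- function(trials, subject = NULL) {
  if (!length(trials)) stopf("need at least one speed's trials")
  if (is.null(names(trials)) || any(!nzchar(names(trials))))
    stopf("trials must be a named list keyed by speed label")
  profiles <- lapply(names(trials), function(lbl) {
    s <- trials[[lbl]]
    fit <- sl_fit("proposed", s, subject = subject,
                  context = sprintf("speed=%s", lbl))
    list(speed_label = lbl, params = fit$params,
         mean_F = mean(s$F), mean_a_r = mean(s$a_r), n = nrow(s))
  })
  structure(profiles, class = "speed_profiles",
            subject_id = if (!is.null(subject)) subject$subject_id else "anon")
}

#' @export
print.speed_profiles <- function(x, ...) {
  cat(sprintf("Speed profiles for subject %s:\n", attr(x, "subject_id")))
  for (p in x)
    cat(sprintf("  %-8s n=%4d  mean_F=%.3f Hz  mean_a_r=%.2f m/s^2  K1=%.4f K2=%.4f\n",
                p$speed_label, p$n, p$mean_F, p$mean_a_r,
                p$params$constants[["K1"]], p$params$constants[["K2"]]))
  invisible(x)
}

#' Joined-speeds calibration
#'
#' Concatenates tuning strides collected at different walking speeds for
#' one subject and sensor position and fits a single constant set — the
#' protocol used to tune models for free-walking (polygon) evaluation.
#'
#' @param model_id model identifier.
#' @param trials list of stride tables (one per speed) to concatenate.
#' @param subject,context,bylemans_variant passed to [sl_fit].
#' @return an `sl_fit` on the concatenated strides.
#' @export
fit_joined <- function(model_id, trials, subject = NULL, context = "",
                       bylemans_variant = c("canonical", "inverse_root")) {
  if (!length(trials)) stopf("need at least one trial")
  joined <- do.call(rbind, lapply(trials, as.data.frame))
  sl_fit(model_id, joined, subject = subject, context = context,
         bylemans_variant = match.arg(bylemans_variant))
}
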