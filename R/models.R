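## Step-length estimators.
##
## All models are pure functions of per-stride features and tunable
## constants and return lengths in meters.  Model ids:
##   base      d = K * a_r^0.1
##   proposed  d = K1 * F + K2 * a_r^0.1
##   mikov     d = (K / F) * (a_max - a_min)^(1/4)
##   bylemans  d = 0.1 * a_mean * (K / F) * (a_max - a_min)^(1/2.7)
##   shin_park d = K1 * F + K2 * a_v + K3
##   sharp_yu  d = K1 * h^K2 * (a_max - a_min)^K3 * F^K4
##
## Frequency convention: F is STRIDE frequency (1/stride duration)
## throughout.  Models published against step frequency are fitted on
## stride features; the factor of two is absorbed by their fitted
## constants.  Models published against vertical acceleration are served
## acceleration-magnitude features by default (the device orientation is
## arbitrary in smartphone data); pass features from a designated vertical
## axis to override.

MODEL_IDS <- c("base", "proposed", "mikov", "bylemans", "shin_park", "sharp_yu")

MODEL_CONSTANTS <- list(
  base = "K", proposed = c("K1", "K2"), mikov = "K", bylemans = "K",
  shin_park = c("K1", "K2", "K3"), sharp_yu = c("K1", "K2", "K3", "K4"))

#' Registered step-length models
#'
#' @return character vector of model identifiers accepted by [sl_estimate]
#'   and [sl_fit].
#' @export
sl_models <- function() MODEL_IDS

#' Tunable-constant set for one model
#'
#' @param model_id model identifier, see [sl_models].
#' @param constants named numeric vector; names must be exactly the
#'   constants the model requires (`K`, or `K1`..`K4`).
#' @param context free-form label of the calibration scope (subject,
#'   position, speed set).
#' @return object of class `model_params`.
#' @export
model_params <- function(model_id, constants, context = "") {
  model_id <- match.arg(model_id, MODEL_IDS)
  need <- MODEL_CONSTANTS[[model_id]]
  if (!setequal(names(constants), need))
    stopf("model '%s' requires constants {%s}, got {%s}", model_id,
          paste(need, collapse = ","),
          paste(names(constants), collapse = ","))
  assert_finite(unlist(constants), "constants")
  structure(list(model_id = model_id,
                 constants = unlist(constants)[need],
                 context = context),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Model '%s'%s: %s\n", x$model_id,
              if (nzchar(x$context)) paste0(" [", x$context, "]") else "",
              paste(sprintf("%s=%.6g", names(x$constants), x$constants),
                    collapse = ", ")))
  invisible(x)
}

#' Subject anthropometrics
#'
#' @param subject_id opaque label.
#' @param height standing height, m (0.5 < h < 2.5).
#' @param leg_length leg length, m.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "anon", height = 1.75,
                            leg_length = 1.0) {
  if (!is.finite(height) || height <= 0.5 || height >= 2.5)
    stopf("height must be in (0.5, 2.5) m, got %g", height)
  structure(list(subject_id = as.character(subject_id),
                 height = height, leg_length = leg_length),
            class = "subject_profile")
}

check_features <- function(features, need) {
  missing <- setdiff(need, names(features))
  if (length(missing))
    stopf("stride features missing column(s): %s",
          paste(missing, collapse = ", "))
  invisible(features)
}

#' Step-length estimators as pure functions
#'
#' Evaluate one of the registered models on per-stride features.
#' `sl_estimate` dispatches on the model id; the `estimate_*` functions are
#' the individual models.
#'
#' @param features data frame of stride features (columns among `F`, `a_r`,
#'   `a_max`, `a_min`, `a_mean`, `a_v`), e.g. from [segment_strides].
#' @param params a [model_params] whose `model_id` picks the estimator.
#' @param subject a [subject_profile]; required by the height-based model.
#' @param bylemans_variant `"canonical"` for
#'   `0.1 * a_mean * (K/F) * a_r^(1/2.7)` or `"inverse_root"` for
#'   `0.1 * a_mean * K * (F * a_r)^(-1/2.7)`; the published typography is
#'   ambiguous, and since K is fitted the variants differ only in shape.
#' @return numeric vector of estimated stride lengths, meters.
#' @export
sl_estimate <- function(features, params, subject = NULL,
                        bylemans_variant = c("canonical", "inverse_root")) {
  stopifnot(inherits(params, "model_params"))
  k <- params$constants
  switch(params$model_id,
    base = estimate_base(features, k[["K"]]),
    proposed = estimate_proposed(features, k[["K1"]], k[["K2"]]),
    mikov = estimate_mikov(features, k[["K"]]),
    bylemans = estimate_bylemans(features, k[["K"]],
                                 variant = match.arg(bylemans_variant)),
    shin_park = estimate_shin_park(features, k[["K1"]], k[["K2"]], k[["K3"]]),
    sharp_yu = {
      if (is.null(subject))
        stopf("the height-based model needs a subject_profile")
      estimate_sharp_yu(features, subject, k[["K1"]], k[["K2"]], k[["K3"]],
                        k[["K4"]])
    })
}

#' @rdname sl_estimate
#' @param K,K1,K2,K3,K4 tunable constants (units absorbed so the output is
#'   in meters).
#' @export
estimate_base <- function(features, K) {
  check_features(features, "a_r")
  if (any(features$a_r < 0)) stopf("a_r must be >= 0")
  if (!is.finite(K)) stopf("K must be finite")
  K * features$a_r^0.1
}

#' @rdname sl_estimate
#' @export
estimate_proposed <- function(features, K1, K2) {
  check_features(features, c("F", "a_r"))
  if (any(features$F <= 0)) stopf("stride frequency must be > 0")
  if (any(features$a_r < 0)) stopf("a_r must be >= 0")
  K1 * features$F + K2 * features$a_r^0.1
}

#' @rdname sl_estimate
#' @export
estimate_mikov <- function(features, K) {
  check_features(features, c("F", "a_max", "a_min"))
  if (any(features$F <= 0)) stopf("stride frequency must be > 0")
  rng <- features$a_max - features$a_min
  if (any(rng < 0)) stopf("a_max - a_min must be >= 0")
  (K / features$F) * rng^0.25
}

#' @rdname sl_estimate
#' @param variant Bylemans grouping, see `bylemans_variant`.
#' @export
estimate_bylemans <- function(features, K,
                              variant = c("canonical", "inverse_root")) {
  variant <- match.arg(variant)
  check_features(features, c("F", "a_max", "a_min", "a_mean"))
  if (any(features$F <= 0)) stopf("stride frequency must be > 0")
  rng <- features$a_max - features$a_min
  if (any(rng < 0)) stopf("a_max - a_min must be >= 0")
  if (any(features$a_mean < 0)) stopf("a_mean must be >= 0")
  if (variant == "canonical")
    0.1 * features$a_mean * (K / features$F) * rng^(1 / 2.7)
  else
    0.1 * features$a_mean * K * (features$F * rng)^(-1 / 2.7)
}

#' @rdname sl_estimate
#' @export
estimate_shin_park <- function(features, K1, K2, K3) {
  check_features(features, c("F", "a_v"))
  if (any(features$F <= 0)) stopf("stride frequency must be > 0")
  if (any(features$a_v < 0)) stopf("a_v must be >= 0")
  K1 * features$F + K2 * features$a_v + K3
}

#' @rdname sl_estimate
#' @export
estimate_sharp_yu <- function(features, subject, K1, K2, K3, K4) {
  stopifnot(inherits(subject, "subject_profile"))
  check_features(features, c("F", "a_max", "a_min"))
  if (any(features$F <= 0)) stopf("stride frequency must be > 0")
  rng <- features$a_max - features$a_min
  if (any(rng <= 0) && K3 < 0)
    stopf("zero acceleration range with a negative exponent")
  K1 * subject$height^K2 * rng^K3 * features$F^K4
}
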