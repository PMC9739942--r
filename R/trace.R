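#' Construct a tri-axial acceleration trace
#'
#' Bundles timestamped tri-axial linear acceleration (gravity already
#' removed, as smartphone APIs and motion-capture-derived datasets provide
#' it) from one body-worn sensor into a validated data frame.
#'
#' @param t sample timestamps in seconds, strictly increasing, length >= 2.
#' @param ax,ay,az linear acceleration per axis, m/s^2.
#' @param position sensor placement label, one of `"upper_arm"`, `"hand"`,
#'   `"pelvis"`, `"thigh"`, `"other"`.
#' @param subject_id opaque subject label.
#' @return an object of class `accel_trace`: a data frame with columns
#'   `t`, `ax`, `ay`, `az` and attributes `position` and `subject_id`.
#' @examples
#' tr <- accel_trace(t = c(0, 0.01, 0.02), ax = c(0, 1, 0),
#'                   ay = c(0, 0, 1), az = c(1, 0, 0))
#' accel_magnitude(tr)
#' @export
accel_trace <- function(t, ax, ay, az, position = "other",
                        subject_id = "anon") {
  n <- length(t)
  if (n < 2L) stopf("an acceleration trace needs at least 2 samples, got %d", n)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stopf("t, ax, ay, az must have equal length")
  assert_finite(t, "t")
  assert_finite(ax, "ax"); assert_finite(ay, "ay"); assert_finite(az, "az")
  dt <- diff(t)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    stopf("timestamps must be strictly increasing; violation at sample %d (t=%g then %g)",
          i + 1L, t[i], t[i + 1L])
  }
  position <- match.arg(position,
                        c("upper_arm", "hand", "pelvis", "thigh", "other"))
  out <- data.frame(t = as.numeric(t), ax = as.numeric(ax),
                    ay = as.numeric(ay), az = as.numeric(az))
  attr(out, "position") <- position
  attr(out, "subject_id") <- as.character(subject_id)
  class(out) <- c("accel_trace", "data.frame")
  out
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("Acceleration trace: %d samples, %.1f s at ~%.0f Hz, position=%s, subject=%s\n",
              nrow(x), diff(range(x$t)),
              (nrow(x) - 1) / diff(range(x$t)),
              attr(x, "position"), attr(x, "subject_id")))
  invisible(x)
}

#' Acceleration magnitude of a trace
#'
#' Euclidean norm of the tri-axial acceleration vector per sample.  The
#' norm is invariant under rotation of the sensor axes, which is what makes
#' magnitude-based step-length models insensitive to smartphone orientation.
#'
#' @param trace an [accel_trace], or a 3-column numeric matrix of axis values.
#' @return numeric vector of per-sample magnitudes, m/s^2 (all >= 0).
#' @export
accel_magnitude <- function(trace) {
  if (inherits(trace, "accel_trace")) {
    m <- cbind(trace$ax, trace$ay, trace$az)
  } else {
    m <- as.matrix(trace)
    if (ncol(m) != 3L) stopf("expected a 3-column matrix of axis values")
  }
  bad <- which(!is.finite(m))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    stopf("non-finite acceleration at sample %d", i)
  }
  sqrt(rowSums(m^2))
}

#' Moving-average smoothing with a trailing, shrinking window
#'
#' Trailing moving average over `window` samples; the first `window - 1`
#' outputs average over the partial window actually available, so the
#' output has the same length as the input and a constant series maps to
#' itself.
#'
#' @param values numeric series.
#' @param window window length in samples (>= 1, <= length of series).
#' @return smoothed series, same length as `values`.
#' @examples
#' moving_average(c(0, 10, 0, 10), 2)  # 0 5 5 5
#' @export
moving_average <- function(values, window = 10L) {
  n <- length(values)
  window <- as.integer(window)
  if (is.na(window) || window < 1L)
    stopf("window must be a positive integer, got %s", deparse(window))
  if (window > n)
    stopf("window (%d) longer than series (%d)", window, n)
  assert_finite(values, "values")
  if (window == 1L) return(as.numeric(values))
  cs <- cumsum(values)
  out <- numeric(n)
  head_n <- seq_len(window - 1L)
  out[head_n] <- cs[head_n] / head_n
  idx <- window:n
  out[idx] <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
  out
}
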