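#' Segmentation settings for stride detection
#'
#' @param min_peak_distance minimum time between step peaks, seconds.
#'   0.3 s admits cadences up to 200 steps/min, far above the tested
#'   walking speeds.
#' @param min_prominence minimum topographic prominence of a step peak,
#'   m/s^2.
#' @param smooth_window moving-average window (samples) applied to the
#'   magnitude before peak picking only; stride features are always
#'   computed on the unsmoothed magnitude so smoothing cannot bias the
#'   acceleration range.
#' @param min_stride_s,max_stride_s physiological gate on stride duration;
#'   candidate strides outside \[0.4, 4\] s are discarded.
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(min_peak_distance = 0.3, min_prominence = 0.5,
                       smooth_window = 10L, min_stride_s = 0.4,
                       max_stride_s = 4) {
  if (min_peak_distance <= 0) stopf("min_peak_distance must be > 0")
  if (min_prominence < 0) stopf("min_prominence must be >= 0")
  structure(list(min_peak_distance = min_peak_distance,
                 min_prominence = min_prominence,
                 smooth_window = as.integer(smooth_window),
                 min_stride_s = min_stride_s,
                 max_stride_s = max_stride_s),
            class = "seg_config")
}

## Local-maximum peak picking with topographic prominence and a minimum
## inter-peak spacing.  Prominence of a peak is its height above the higher
## of the two deepest valleys separating it from taller terrain on either
## side (standard topographic definition).  Candidates are accepted in
## decreasing height order; a candidate closer than min_distance samples to
## an already-accepted peak is dropped.
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  if (min_prominence > 0) {
    prom <- vapply(cand, function(i) {
      h <- x[i]
      # walk left until terrain exceeds h; track lowest point on the way
      left_min <- h
      j <- i - 1L
      while (j >= 1L && x[j] <= h) {
        if (x[j] < left_min) left_min <- x[j]
        j <- j - 1L
      }
      if (j < 1L && left_min == h) left_min <- min(x[1:i])
      right_min <- h
      j <- i + 1L
      while (j <= n && x[j] <= h) {
        if (x[j] < right_min) right_min <- x[j]
        j <- j + 1L
      }
      if (j > n && right_min == h) right_min <- min(x[i:n])
      h - max(left_min, right_min)
    }, numeric(1))
    cand <- cand[prom >= min_prominence]
    if (!length(cand)) return(integer(0))
  }
  keep <- logical(length(cand))
  ord <- order(x[cand], decreasing = TRUE)
  taken <- integer(0)
  for (k in ord) {
    if (!length(taken) || all(abs(cand[k] - taken) >= min_distance)) {
      keep[k] <- TRUE
      taken <- c(taken, cand[k])
    }
  }
  sort(cand[keep])
}

#' Per-stride features from a magnitude window
#'
#' Computes the feature tuple every step-length model consumes from the
#' (unsmoothed) acceleration-magnitude samples of one stride.
#'
#' @param mag_window magnitude samples within the stride, length >= 2.
#' @param t_start,t_end stride interval bounds, seconds (`t_end > t_start`).
#' @return one-row data frame with columns `duration` (s), `F` (stride
#'   frequency, Hz), `a_max`, `a_min`, `a_r` (range), `a_mean` (mean),
#'   all m/s^2, and `a_v` (population variance, (m/s^2)^2).
#' @details The variance is the population variance (divide by n): each
#'   stride window is the full population of its samples, and a fixed
#'   convention keeps fitted constants comparable across implementations.
#' @examples
#' stride_features(c(8, 12), 0, 0.5)  # a_r = 4, a_v = 4, F = 2
#' @export
stride_features <- function(mag_window, t_start, t_end) {
  if (length(mag_window) < 2L)
    stopf("stride window must contain at least 2 samples")
  duration <- t_end - t_start
  if (!is.finite(duration) || duration <= 0)
    stopf("degenerate stride window: duration %g s", duration)
  assert_finite(mag_window, "mag_window")
  m <- as.numeric(mag_window)
  a_max <- max(m); a_min <- min(m)
  data.frame(duration = duration, F = 1 / duration,
             a_max = a_max, a_min = a_min, a_r = a_max - a_min,
             a_mean = mean(abs(m)),
             a_v = mean((m - mean(m))^2))
}

#' Segment a magnitude series into strides
#'
#' Detects step peaks on the smoothed acceleration magnitude (local maxima
#' with a minimum prominence and minimum inter-peak distance) and pairs
#' peaks of the same parity: stride i spans step peak i to step peak i+2,
#' so one stride covers two steps — matching treadmill references that are
#' stride lengths of one limb.  Features are computed on the unsmoothed
#' magnitude within each interval.
#'
#' @param mag acceleration magnitude series, m/s^2.
#' @param t timestamps, seconds, same length as `mag`.
#' @param config a [seg_config].
#' @return data frame of class `stride_table`: one row per stride with
#'   columns `start_idx`, `end_idx` (1-based, half-open `[start, end)`),
#'   `t_start`, `t_end` (seconds),
#'   the [stride_features] columns, and `d_ref` (NA; filled by reference
#'   pipelines).  Zero rows (with a warning) when fewer than 3 peaks are
#'   found.
#' @export
segment_strides <- function(mag, t, config = seg_config()) {
  if (length(mag) != length(t))
    stopf("mag and t must have equal length")
  fs <- (length(t) - 1) / diff(range(t))
  sm <- moving_average(mag, min(config$smooth_window, length(mag)))
  peaks <- find_peaks(sm,
                      min_distance = max(1L, round(config$min_peak_distance * fs)),
                      min_prominence = config$min_prominence)
  if (length(peaks) < 3L) {
    warnf("fewer than 3 step peaks detected (%d); no strides segmented",
          length(peaks))
    return(empty_stride_table())
  }
  ## same-parity pairing: peak i -> peak i+2
  starts <- peaks[seq_len(length(peaks) - 2L)]
  ends <- peaks[3:length(peaks)]
  rows <- lapply(seq_along(starts), function(k) {
    s <- starts[k]; e <- ends[k]
    dur <- t[e] - t[s]
    if (dur < config$min_stride_s || dur > config$max_stride_s) return(NULL)
    cbind(data.frame(start_idx = s, end_idx = e, t_start = t[s], t_end = t[e]),
          stride_features(mag[s:(e - 1L)], t[s], t[e]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warnf("all stride candidates outside the [%g, %g] s duration gate",
          config$min_stride_s, config$max_stride_s)
    return(empty_stride_table())
  }
  ## keep alternate (non-overlapping) strides of one parity, starting at
  ## the first kept candidate
  out <- do.call(rbind, rows)
  keep <- logical(nrow(out))
  last_end <- -Inf
  for (i in seq_len(nrow(out))) {
    if (out$start_idx[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- out$end_idx[i]
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$d_ref <- NA_real_
  class(out) <- c("stride_table", "data.frame")
  out
}

empty_stride_table <- function() {
  out <- data.frame(start_idx = integer(0), end_idx = integer(0),
                    t_start = numeric(0), t_end = numeric(0),
                    duration = numeric(0), F = numeric(0),
                    a_max = numeric(0), a_min = numeric(0),
                    a_r = numeric(0), a_mean = numeric(0),
                    a_v = numeric(0), d_ref = numeric(0))
  class(out) <- c("stride_table", "data.frame")
  out
}

#' @export
print.stride_table <- function(x, ...) {
  cat(sprintf("Stride table: %d strides", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", mean F = %.3f Hz, mean a_r = %.2f m/s^2", mean(x$F),
                mean(x$a_r)))
    if (any(is.finite(x$d_ref)))
      cat(sprintf(", %d with reference lengths", sum(is.finite(x$d_ref))))
  }
  cat("\n")
  invisible(x)
}
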