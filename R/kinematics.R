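#' Construct an optical-marker trajectory
#'
#' @param marker_id marker label (anatomical markers `M1`–`M8`; the heel
#'   marker is `M7` by convention; `M9`+ are device markers).
#' @param t sample timestamps, seconds, strictly increasing.
#' @param x,y,z position, meters.  Convention throughout the package:
#'   x–y is the ground plane, z is vertical.
#' @return object of class `marker_trajectory` (data frame `t,x,y,z` with a
#'   `marker_id` attribute).
#' @export
marker_trajectory <- function(marker_id, t, x, y, z) {
  n <- length(t)
  if (n < 2L) stopf("trajectory needs at least 2 samples")
  if (length(x) != n || length(y) != n || length(z) != n)
    stopf("t, x, y, z must have equal length")
  assert_finite(t, "t")
  assert_finite(x, "x"); assert_finite(y, "y"); assert_finite(z, "z")
  if (any(diff(t) <= 0)) stopf("timestamps must be strictly increasing")
  out <- data.frame(t = as.numeric(t), x = as.numeric(x),
                    y = as.numeric(y), z = as.numeric(z))
  attr(out, "marker_id") <- as.character(marker_id)
  class(out) <- c("marker_trajectory", "data.frame")
  out
}

#' Finite-difference derivative of a sampled series
#'
#' Central differences at interior points, one-sided (forward/backward)
#' differences at the endpoints; exact for linear series everywhere and for
#' quadratics at interior points.
#'
#' @param values numeric series, length >= 3.
#' @param t timestamps, strictly increasing, same length.
#' @return derivative series, same length as `values`.
#' @export
finite_difference <- function(values, t) {
  n <- length(values)
  if (n < 3L) stopf("finite differences need at least 3 points, got %d", n)
  if (length(t) != n) stopf("values and t must have equal length")
  if (any(diff(t) <= 0)) stopf("duplicate or decreasing timestamps")
  assert_finite(values, "values")
  d <- numeric(n)
  i <- 2:(n - 1L)
  d[i] <- (values[i + 1L] - values[i - 1L]) / (t[i + 1L] - t[i - 1L])
  d[1L] <- (values[2L] - values[1L]) / (t[2L] - t[1L])
  d[n] <- (values[n] - values[n - 1L]) / (t[n] - t[n - 1L])
  d
}

#' Velocity and acceleration of a marker trajectory
#'
#' Differentiates the position per axis (finite differences), smooths with
#' a trailing moving average, then differentiates and smooths again for
#' acceleration.  Differentiation precedes filtering at each stage.
#'
#' @param traj a [marker_trajectory].
#' @param filter_window moving-average window in samples (default 10).
#' @return list of class `kinematic_series`: `t`, `velocity` (n x 3 matrix,
#'   m/s), `acceleration` (n x 3 matrix, m/s^2), `speed` (horizontal
#'   ground-plane speed, m/s).
#' @export
marker_kinematics <- function(traj, filter_window = 10L) {
  stopifnot(inherits(traj, "marker_trajectory"))
  pos <- cbind(traj$x, traj$y, traj$z)
  vel <- apply(pos, 2L, function(col)
    moving_average(finite_difference(col, traj$t),
                   min(filter_window, nrow(pos))))
  acc <- apply(vel, 2L, function(col)
    moving_average(finite_difference(col, traj$t),
                   min(filter_window, nrow(pos))))
  colnames(vel) <- colnames(acc) <- c("x", "y", "z")
  structure(list(t = traj$t, velocity = vel, acceleration = acc,
                 speed = sqrt(vel[, 1L]^2 + vel[, 2L]^2),
                 marker_id = attr(traj, "marker_id")),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("Kinematics of marker %s: %d samples, mean horizontal speed %.3f m/s\n",
              x$marker_id, length(x$t), mean(x$speed)))
  invisible(x)
}

#' Reference stride lengths from a heel trajectory
#'
#' Detects stance phases as runs where the filtered horizontal heel speed
#' stays below a threshold for a minimum duration, and takes the stride
#' length as the horizontal displacement between centroids of consecutive
#' stance phases.  On a treadmill the foot rides the belt during stance, so
#' the belt displacement `belt_speed * dt` between stance centroids is
#' added when `belt_speed` is given.
#'
#' @param heel heel-marker [marker_trajectory].
#' @param speed_threshold stance speed threshold, m/s (default 0.2).
#' @param min_stance minimum stance duration, seconds (default 0.1).
#' @param belt_speed treadmill belt speed, m/s; `NULL` for overground.
#' @param filter_window smoothing window for the speed signal (samples).
#' @return data frame with one row per stride: `t_start`, `t_end` (stance
#'   centroid times), `duration`, `d_ref` (m).  Zero rows plus a warning
#'   when fewer than 2 stance phases are found.
#' @export
reference_strides <- function(heel, speed_threshold = 0.2, min_stance = 0.1,
                              belt_speed = NULL, filter_window = 10L) {
  kin <- marker_kinematics(heel, filter_window)
  below <- kin$speed < speed_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  stance <- which(r$values)
  keep <- stance[vapply(stance, function(k)
    kin$t[ends[k]] - kin$t[starts[k]] >= min_stance, logical(1))]
  if (length(keep) < 2L) {
    warnf("fewer than 2 stance phases detected (%d); no reference strides",
          length(keep))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), d_ref = numeric(0)))
  }
  cent <- t(vapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    c(t = mean(kin$t[idx]), x = mean(heel$x[idx]), y = mean(heel$y[idx]))
  }, numeric(3)))
  m <- nrow(cent) - 1L
  dt <- diff(cent[, "t"])
  disp <- sqrt(diff(cent[, "x"])^2 + diff(cent[, "y"])^2)
  if (!is.null(belt_speed)) disp <- disp + belt_speed * dt
  data.frame(t_start = cent[seq_len(m), "t"],
             t_end = cent[seq_len(m) + 1L, "t"],
             duration = dt, d_ref = disp)
}
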