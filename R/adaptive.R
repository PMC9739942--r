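#' Adaptive estimation settings
#'
#' @param N strides per decision window (>= 1).  Every `N` strides the
#'   selector re-matches the window's input averages against the stored
#'   speed profiles; at typical cadences of ~1 stride/s the default of 10
#'   re-decides about every ten seconds.
#' @return list of class `adaptive_config`.
#' @export
adaptive_config <- function(N = 10L) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stopf("N must be a positive integer")
  structure(list(N = N), class = "adaptive_config")
}

## z-scoring scales for profile matching: the pooled spread of the profile
## centroids per feature (SD across centroids; 1 when degenerate) so that
## frequency (Hz) and acceleration range (m/s^2) are comparable.
profile_scales <- function(profiles) {
  fs <- vapply(profiles, `[[`, numeric(1), "mean_F")
  as <- vapply(profiles, `[[`, numeric(1), "mean_a_r")
  sf <- stats::sd(fs); sa <- stats::sd(as)
  c(F = if (is.finite(sf) && sf > 0) sf else 1,
    a_r = if (is.finite(sa) && sa > 0) sa else 1)
}

#' Select the speed profile matching a stride window
#'
#' Computes the window's mean stride frequency and mean
#' acceleration-magnitude range, z-scores both using the pooled spread of
#' the profile centroids, and returns the profile with the smallest
#' Euclidean distance.  Ties go to the profile with the lower stored mean
#' stride frequency, independent of list order.
#'
#' @param window_strides non-empty stride table (needs `F` and `a_r`).
#' @param profiles a [fit_speed_profiles] result (or plain list of
#'   profiles).
#' @return the selected profile (list with `speed_label`, `params`,
#'   `mean_F`, `mean_a_r`).
#' @export
select_profile <- function(window_strides, profiles) {
  if (!length(profiles)) stopf("empty profile list")
  if (!nrow(window_strides)) stopf("empty stride window")
  sc <- profile_scales(profiles)
  wF <- mean(window_strides$F) / sc[["F"]]
  wa <- mean(window_strides$a_r) / sc[["a_r"]]
  d2 <- vapply(profiles, function(p)
    (p$mean_F / sc[["F"]] - wF)^2 + (p$mean_a_r / sc[["a_r"]] - wa)^2,
    numeric(1))
  best <- which(d2 <= min(d2) + 1e-12)
  if (length(best) > 1L) {
    fs <- vapply(profiles[best], `[[`, numeric(1), "mean_F")
    best <- best[which.min(fs)]
  }
  profiles[[best[1L]]]
}

#' Adaptive step-length estimation
#'
#' Processes strides in consecutive windows of `N`; for each window the
#' matching speed profile is selected from the window's own input averages
#' (causal — no look-ahead past the window) and the adaptive model is
#' evaluated with that profile's constants.
#'
#' @param strides stride table ordered in time.
#' @param profiles a [fit_speed_profiles] result.
#' @param config an [adaptive_config].
#' @return object of class `sl_adaptive`: data frame with one row per
#'   stride — `d_est` (m), `speed_label` (chosen profile), `window` (the
#'   decision-window index).
#' @export
estimate_adaptive <- function(strides, profiles, config = adaptive_config()) {
  stopifnot(inherits(config, "adaptive_config"))
  n <- nrow(strides)
  if (!n) stopf("no strides to estimate")
  win <- ceiling(seq_len(n) / config$N)
  out <- data.frame(d_est = numeric(n), speed_label = character(n),
                    window = win)
  for (w in unique(win)) {
    idx <- which(win == w)
    prof <- select_profile(strides[idx, , drop = FALSE], profiles)
    out$d_est[idx] <- estimate_proposed(strides[idx, , drop = FALSE],
                                        prof$params$constants[["K1"]],
                                        prof$params$constants[["K2"]])
    out$speed_label[idx] <- prof$speed_label
  }
  class(out) <- c("sl_adaptive", "data.frame")
  out
}

#' @export
print.sl_adaptive <- function(x, ...) {
  tab <- table(x$speed_label)
  cat(sprintf("Adaptive step-length estimates: %d strides, %d decision windows\n",
              nrow(x), length(unique(x$window))))
  cat("  profile usage:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
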