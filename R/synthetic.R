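## Seeded synthetic gait: IMU traces, marker trajectories, benchmark
## rosters.  The generators emulate the structure of treadmill / polygon
## gait recordings (three treadmill speeds, four sensor positions, a
## 21.64 m rectangular loop, heel-marker references) so the whole pipeline
## is testable without recorded data.

## default speed -> stride frequency (Hz) and amplitude-scale mappings;
## monotone in speed by construction.  The 3.3 / 4.6 / 5.9 km/h treadmill
## speeds map to 0.80 / 0.92 / 1.05 Hz.
SPEED_F <- c(slow = 0.80, normal = 0.92, fast = 1.05, polygon = 0.90)
SPEED_AMP <- c(slow = 0.80, normal = 1.00, fast = 1.25, polygon = 0.95)

## position-dependent magnitude amplitudes, m/s^2 (hand > thigh >
## upper_arm > pelvis: distal segments swing harder than the trunk)
POSITION_AMP <- c(hand = 4.0, thigh = 3.0, upper_arm = 2.5, pelvis = 2.0,
                  other = 2.5)

#' Define a synthetic gait scenario
#'
#' A `gait_scenario` is the full recipe for one simulated trial: walking
#' speed (or an explicit stride frequency), sensor position, signal
#' amplitude and noise, the truth model that maps stride features to
#' reference stride lengths, and the route (treadmill or a 21.64 m
#' rectangular polygon).  Every stochastic draw downstream is governed by
#' `seed`, so a scenario is a reproducible experiment definition.
#'
#' @param seed integer seed; same seed, same scenario output, bitwise.
#' @param n_strides number of strides to simulate (>= 1).
#' @param speed one of `"slow"`, `"normal"`, `"fast"`, `"polygon"`; sets
#'   the default stride frequency (0.80 / 0.92 / 1.05 / 0.90 Hz) and an
#'   amplitude scale, both monotone in speed.
#' @param stride_frequency override of the mean stride frequency, Hz.
#' @param position sensor placement; sets the default magnitude amplitude
#'   (hand 4.0 > thigh 3.0 > upper_arm 2.5 > pelvis 2.0 m/s^2).
#' @param amplitude override of the step-harmonic amplitude, m/s^2.
#' @param noise_sd i.i.d. Gaussian noise on the magnitude, m/s^2.
#' @param sampling_rate Hz (>= 20; default 100).
#' @param truth_model `"linear_in_features"` (reference lengths
#'   `d = K1 * F + K2 * a_r^0.1 + eps`) or `"pendulum"` (inverted-pendulum
#'   relation on leg length with jitter).
#' @param K1,K2 true constants of the linear truth model.
#' @param length_noise_sd SD of the reference-length noise `eps`, m.
#' @param leg_length leg length for the pendulum truth model, m.
#' @param height subject height, m.
#' @param f_jitter per-stride CV of stride duration (default 4%, a typical
#'   stride-time variability for steady walking).
#' @param amp_jitter per-stride CV of the amplitude (default 10%).
#' @param route `"treadmill"` or `"polygon"`.
#' @param loop_length_m polygon perimeter, m (default 21.64).
#' @param subject_id label.
#' @return list of class `gait_scenario`.
#' @export
gait_scenario <- function(seed = 1L, n_strides = 50L, speed = "normal",
                          stride_frequency = NULL, position = "pelvis",
                          amplitude = NULL, noise_sd = 0.3,
                          sampling_rate = 100,
                          truth_model = c("linear_in_features", "pendulum"),
                          K1 = 0.35, K2 = 0.20, length_noise_sd = 0.02,
                          leg_length = 1.0, height = 1.75,
                          f_jitter = 0.04, amp_jitter = 0.10,
                          route = c("treadmill", "polygon"),
                          loop_length_m = 21.64, subject_id = "S1") {
  speed <- match.arg(speed, names(SPEED_F))
  position <- match.arg(position, names(POSITION_AMP))
  n_strides <- as.integer(n_strides)
  if (n_strides < 1L) stopf("n_strides must be >= 1")
  if (sampling_rate < 20) stopf("sampling_rate must be >= 20 Hz")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(
    seed = as.integer(seed), n_strides = n_strides, speed = speed,
    stride_frequency = if (is.null(stride_frequency)) SPEED_F[[speed]]
                       else stride_frequency,
    position = position,
    amplitude = if (is.null(amplitude))
      POSITION_AMP[[position]] * SPEED_AMP[[speed]] else amplitude,
    noise_sd = noise_sd, sampling_rate = sampling_rate,
    truth_model = match.arg(truth_model), K1 = K1, K2 = K2,
    length_noise_sd = length_noise_sd, leg_length = leg_length,
    height = height, f_jitter = f_jitter, amp_jitter = amp_jitter,
    route = match.arg(route), loop_length_m = loop_length_m,
    subject_id = as.character(subject_id)),
    class = "gait_scenario")
}

#' @export
print.gait_scenario <- function(x, ...) {
  cat(sprintf("Gait scenario: %d strides @ %.2f Hz (%s, %s), amp %.2f m/s^2, noise %.2f, route %s, seed %d\n",
              x$n_strides, x$stride_frequency, x$speed, x$position,
              x$amplitude, x$noise_sd, x$route, x$seed))
  invisible(x)
}

## per-stride durations/amplitudes + the random rotation, drawn under the
## scenario seed.  Noise draws are standard normal and scaled by the
## configured SDs afterwards, so scenarios differing only in a noise SD
## share the same underlying draws.
scenario_draws <- function(sc) {
  with_seed(sc$seed, {
    dur <- (1 / sc$stride_frequency) *
      pmax(0.3, 1 + sc$f_jitter * stats::rnorm(sc$n_strides))
    list(dur = dur,
         amp = sc$amplitude *
           pmax(0.2, 1 + sc$amp_jitter * stats::rnorm(sc$n_strides)),
         rot = random_rotation(),
         mag_noise_z = stats::rnorm(
           ceiling(sc$sampling_rate * (sum(dur) + 3))),
         len_noise_z = stats::rnorm(sc$n_strides),
         stance_jitter_z = stats::rnorm(sc$n_strides + 1L))
  })
}

## uniform random rotation via QR of a Gaussian matrix, det +1
random_rotation <- function() {
  m <- matrix(stats::rnorm(9L), 3L)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Generate a synthetic acceleration trace with ground truth
#'
#' Builds the acceleration magnitude as a baseline plus a harmonic at the
#' step frequency (2F), a weaker harmonic at the stride frequency F (the
#' left/right asymmetry that distinguishes the two steps of a stride), and
#' Gaussian noise; the magnitude is then rotated into three axes by a
#' fixed seeded rotation, so the magnitude itself is rotation-controlled.
#' Ground-truth stride records carry features computed from the generated
#' magnitude within each stride window, plus reference lengths from the
#' scenario's truth model.
#'
#' @param scenario a [gait_scenario].
#' @return list of class `synthetic_trace`: `trace` ([accel_trace]),
#'   `strides` (ground-truth `stride_table` with `d_ref` filled),
#'   `scenario`.
#' @export
generate_trace <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  sc <- scenario
  dr <- scenario_draws(sc)
  bounds <- c(0, cumsum(dr$dur))
  total <- bounds[length(bounds)]
  dt <- 1 / sc$sampling_rate
  t <- seq(0, total + 1, by = dt)  # one trailing second past the last stride
  ## per-sample stride index and local phase in [0,1)
  idx <- findInterval(t, bounds, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > sc$n_strides] <- sc$n_strides
  phase <- (t - bounds[idx]) / dr$dur[idx]
  amp <- dr$amp[idx]
  baseline <- 1.2 * sc$amplitude + 1
  mag <- baseline +
    amp * sin(2 * pi * 2 * phase - pi / 2) +
    0.25 * amp * sin(2 * pi * phase) +
    sc$noise_sd * dr$mag_noise_z[seq_along(t)]
  mag <- pmax(mag, 0.01)
  axes <- t(dr$rot %*% rbind(mag, 0, 0))
  trace <- accel_trace(t, axes[, 1L], axes[, 2L], axes[, 3L],
                       position = sc$position, subject_id = sc$subject_id)
  ## ground-truth stride records on the generated magnitude
  rows <- lapply(seq_len(sc$n_strides), function(i) {
    s <- findInterval(bounds[i], t) ; e <- findInterval(bounds[i + 1L], t)
    if (e - s < 2L) return(NULL)
    cbind(data.frame(start_idx = s, end_idx = e, t_start = t[s], t_end = t[e]),
          stride_features(mag[s:(e - 1L)], t[s], t[e]))
  })
  strides <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  eps <- sc$length_noise_sd * dr$len_noise_z[seq_len(nrow(strides))]
  strides$d_ref <- if (sc$truth_model == "linear_in_features") {
    sc$K1 * strides$F + sc$K2 * strides$a_r^0.1 + eps
  } else {
    ## inverted pendulum: step length from the vertical excursion of the
    ## center of mass, h = L (1 - cos(theta)); doubled for a stride
    theta <- 0.35 * (1 + 0.1 * dr$len_noise_z[seq_len(nrow(strides))])
    h <- sc$leg_length * (1 - cos(theta))
    2 * 2 * sqrt(pmax(2 * sc$leg_length * h - h^2, 0))
  }
  rownames(strides) <- NULL
  class(strides) <- c("stride_table", "data.frame")
  structure(list(trace = trace, strides = strides, scenario = sc),
            class = "synthetic_trace")
}

#' @export
print.synthetic_trace <- function(x, ...) {
  print(x$scenario)
  print(x$trace)
  print(x$strides)
  invisible(x)
}

## position along a rectangular loop of given perimeter at arc length s;
## aspect ratio fixed at 2.6:1
polygon_xy <- function(s, perimeter) {
  a <- perimeter / (2 * (1 + 1 / 2.6))   # long side
  b <- perimeter / 2 - a                 # short side
  s <- s %% perimeter
  out <- matrix(0, length(s), 2L)
  for (i in seq_along(s)) {
    u <- s[i]
    out[i, ] <-
      if (u < a) c(u, 0)
      else if (u < a + b) c(a, u - a)
      else if (u < 2 * a + b) c(a - (u - a - b), b)
      else c(0, b - (u - 2 * a - b))
  }
  out
}

#' Generate synthetic marker trajectories
#'
#' Produces the eight anatomical-marker trajectories of one simulated
#' trial.  The heel marker (`M7`) alternates flat stance segments with
#' smooth swing interpolation, so stance-based reference stride lengths
#' recover the configured lengths; the other markers are phase-offset
#' sinusoids superimposed on the forward progression.  Treadmill trials
#' are expressed in the belt frame — stance points stay put and net
#' forward displacement is near zero — so belt compensation
#' (`belt_speed * stride time`) reconstructs the stride length; polygon
#' trials advance around a rectangular loop of the configured perimeter.
#'
#' @param scenario a [gait_scenario].
#' @param stride_length_m configured stride length, m (default 1.30);
#'   recycled to `n_strides`.
#' @param stance_fraction fraction of the stride spent in stance
#'   (default 0.35).
#' @param stance_jitter_sd positional jitter of stance points, m
#'   (default 0: exact geometry).
#' @param marker_noise_sd optical measurement noise per coordinate, m
#'   (default 0.0005, the sub-millimeter accuracy typical of active-marker
#'   systems; set 0 for exact geometry).
#' @return list of class `synthetic_markers`: `markers` (named list of
#'   [marker_trajectory], `M1`–`M8`), `stride_lengths` (truth, m),
#'   `belt_speed` (m/s, treadmill only), `scenario`.
#' @export
generate_markers <- function(scenario, stride_length_m = 1.30,
                             stance_fraction = 0.35,
                             stance_jitter_sd = 0,
                             marker_noise_sd = 0.0005) {
  stopifnot(inherits(scenario, "gait_scenario"))
  sc <- scenario
  dr <- scenario_draws(sc)
  n <- sc$n_strides
  lens <- rep_len(stride_length_m, n)
  durs <- dr$dur
  bounds <- c(0, cumsum(durs))
  dt <- 1 / sc$sampling_rate
  t <- seq(0, bounds[n + 1L] + durs[n] * stance_fraction, by = dt)
  treadmill <- sc$route == "treadmill"
  ## stance anchor arc positions: cumulative stride lengths (overground /
  ## polygon) or fixed (belt frame)
  anchors <- if (treadmill) rep(0, n + 1L) else c(0, cumsum(lens))
  if (stance_jitter_sd > 0)
    anchors <- anchors + stance_jitter_sd * dr$stance_jitter_z
  ## heel arc-length position vs time: flat during stance, smoothstep swing
  arc <- numeric(length(t))
  z_heel <- numeric(length(t))
  for (i in seq_len(n + 1L)) {
    st0 <- bounds[i]
    dur_i <- durs[min(i, n)]
    st1 <- st0 + stance_fraction * dur_i
    in_st <- t >= st0 & t < st1
    arc[in_st] <- anchors[i]
    if (i <= n) {
      sw <- t >= st1 & t < bounds[i + 1L]
      u <- (t[sw] - st1) / (bounds[i + 1L] - st1)
      s3 <- u * u * (3 - 2 * u)            # smoothstep: C1 at both ends
      ## belt frame: stance anchors coincide, so the swing needs a forward
      ## excursion-and-return bump to separate stance phases in time
      bump <- if (treadmill) 0.4 * mean(lens) * sin(pi * u)^2 else 0
      arc[sw] <- anchors[i] + (anchors[i + 1L] - anchors[i]) * s3 + bump
      z_heel[sw] <- 0.06 * sin(pi * u)^2   # swing foot clearance, m
    }
  }
  arc[t >= bounds[n + 1L] + stance_fraction * durs[n]] <- anchors[n + 1L]
  heel_xy <- if (sc$route == "polygon")
    polygon_xy(arc, sc$loop_length_m)
  else
    cbind(arc, 0)
  markers <- list(M7 = marker_trajectory("M7", t, heel_xy[, 1L],
                                         heel_xy[, 2L], z_heel))
  ## remaining landmarks: forward progression + phase-offset sinusoids
  mean_len <- mean(lens); mean_dur <- mean(durs)
  fwd_speed <- if (treadmill) 0 else mean_len / mean_dur
  F0 <- 1 / mean_dur
  specs <- list(M1 = c(z0 = 1.45, ax = 0.02, f = 1), # shoulder
                M2 = c(z0 = 1.15, ax = 0.10, f = 1), # elbow
                M3 = c(z0 = 0.90, ax = 0.18, f = 1), # wrist
                M4 = c(z0 = 1.00, ax = 0.03, f = 2), # hip/pelvis
                M5 = c(z0 = 0.50, ax = 0.12, f = 1), # knee
                M6 = c(z0 = 0.10, ax = 0.22, f = 1), # ankle
                M8 = c(z0 = 0.05, ax = 0.25, f = 1)) # toes
  ph <- 0
  for (id in names(specs)) {
    sp <- specs[[id]]
    ph <- ph + pi / 4
    x <- fwd_speed * t + sp[["ax"]] * sin(2 * pi * sp[["f"]] * F0 * t + ph)
    z <- sp[["z0"]] + 0.03 * sin(2 * pi * 2 * F0 * t + ph)
    y <- 0.02 * sin(2 * pi * F0 * t + ph / 2)
    markers[[id]] <- marker_trajectory(id, t, x, y, z)
  }
  if (marker_noise_sd > 0) {
    markers <- with_seed((sc$seed * 977L + 131071L) %% .Machine$integer.max, {
      lapply(markers, function(m) {
        noise <- matrix(stats::rnorm(3L * nrow(m), sd = marker_noise_sd),
                        ncol = 3L)
        marker_trajectory(attr(m, "marker_id"), m$t, m$x + noise[, 1L],
                          m$y + noise[, 2L], m$z + noise[, 3L])
      })
    })
  }
  belt <- if (treadmill) mean_len / mean_dur else NULL
  structure(list(markers = markers[paste0("M", 1:8)],
                 ## on the belt the true stride length is belt speed times
                 ## the (jittered) stride time, not the nominal constant
                 stride_lengths = if (treadmill) belt * durs else lens,
                 belt_speed = belt,
                 scenario = sc),
            class = "synthetic_markers")
}

#' Generate a benchmark roster of synthetic trials
#'
#' Writes a directory of CSV trials emulating a benchmark layout:
#' `n_subjects` x 4 sensor positions x 4 trials (slow / normal / fast
#' treadmill + polygon), each an acceleration-trace CSV plus a
#' ground-truth stride CSV, with a manifest listing subject, position,
#' speed, seed and truth constants per trial.
#'
#' @param seed master seed; per-trial seeds are derived deterministically.
#' @param out_dir output directory (created if missing).
#' @param n_subjects subjects in the roster (default 3).
#' @param n_strides strides per trial (default 40).
#' @return invisibly, the manifest data frame (also written to
#'   `manifest.csv`).
#' @export
generate_benchmark_suite <- function(seed, out_dir, n_subjects = 3L,
                                     n_strides = 40L) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stopf("cannot create output directory %s", out_dir)
  positions <- c("upper_arm", "hand", "pelvis", "thigh")
  speeds <- c("slow", "normal", "fast", "polygon")
  rows <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) for (p in positions) for (v in speeds) {
    k <- k + 1L
    trial_seed <- (as.integer(seed) * 1000L + k) %% .Machine$integer.max
    sc <- gait_scenario(seed = trial_seed, n_strides = n_strides, speed = v,
                        position = p,
                        route = if (v == "polygon") "polygon" else "treadmill",
                        subject_id = sprintf("S%02d", s))
    g <- generate_trace(sc)
    stem <- sprintf("S%02d_%s_%s", s, p, v)
    trace_file <- file.path(out_dir, paste0(stem, "_trace.csv"))
    stride_file <- file.path(out_dir, paste0(stem, "_strides.csv"))
    write_accel_trace(g$trace, trace_file)
    utils::write.csv(as.data.frame(g$strides), stride_file,
                     row.names = FALSE)
    rows[[k]] <- data.frame(subject = sc$subject_id, position = p, speed = v,
                            route = sc$route, seed = trial_seed,
                            n_strides = nrow(g$strides),
                            K1 = sc$K1, K2 = sc$K2,
                            trace_file = basename(trace_file),
                            stride_file = basename(stride_file))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
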