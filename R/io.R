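#' Standard gravity, m/s^2, for g-unit conversion
#' @export
STANDARD_GRAVITY <- 9.80665

#' Read an acceleration trace from CSV
#'
#' Expects a header with a time column and three acceleration columns
#' (default `t,ax,ay,az`); other layouts are handled by the `mapping`
#' argument rather than a hard-coded schema, since recorded datasets vary.
#'
#' @param path CSV file path.
#' @param mapping named character vector remapping `c(t=, ax=, ay=, az=)`
#'   to the file's column names.
#' @param units `"ms2"` (values already m/s^2) or `"g"` (multiplied by
#'   9.80665).
#' @param position,subject_id metadata attached to the trace.
#' @return an [accel_trace].
#' @export
read_accel_trace <- function(path, mapping = c(t = "t", ax = "ax",
                                               ay = "ay", az = "az"),
                             units = c("ms2", "g"),
                             position = "other", subject_id = "anon") {
  units <- match.arg(units)
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stopf("empty trace file: %s", path)
  missing <- setdiff(unname(mapping), names(df))
  if (length(missing))
    stopf("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  get <- function(k) {
    v <- suppressWarnings(as.numeric(df[[mapping[[k]]]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("%s: unparseable or non-finite %s at data row %d", path, k,
            bad[1L])
    v
  }
  t <- get("t")
  dtt <- diff(t)
  if (any(dtt <= 0)) {
    i <- which(dtt <= 0)[1L]
    stopf("%s: non-increasing timestamp at data row %d", path, i + 1L)
  }
  scale <- if (units == "g") STANDARD_GRAVITY else 1
  accel_trace(t, get("ax") * scale, get("ay") * scale, get("az") * scale,
              position = position, subject_id = subject_id)
}

#' Write an acceleration trace to CSV
#'
#' @param trace an [accel_trace].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_accel_trace <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  utils::write.csv(as.data.frame(trace)[c("t", "ax", "ay", "az")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read marker trajectories from long-form CSV
#'
#' Long format: header `t,marker_id,x,y,z`, positions in meters.
#'
#' @param path CSV path.
#' @return named list of [marker_trajectory], keyed by marker id.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path)
  need <- c("t", "marker_id", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  lapply(split(df, df$marker_id), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    marker_trajectory(d$marker_id[1L], d$t, d$x, d$y, d$z)
  })
}

#' Write marker trajectories to long-form CSV
#'
#' @param markers named list of [marker_trajectory].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_markers <- function(markers, path) {
  long <- do.call(rbind, lapply(markers, function(m)
    data.frame(t = m$t, marker_id = attr(m, "marker_id"),
               x = m$x, y = m$y, z = m$z)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write fitted constants to a parameter file
#'
#' Structured JSON holding model id, calibration context, constants and
#' fit diagnostics; one object per fit.
#'
#' @param fits a single `sl_fit` / [model_params], or a list of them.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_params <- function(fits, path) {
  one <- function(f) {
    if (inherits(f, "sl_fit"))
      list(model_id = f$params$model_id, context = f$params$context,
           constants = as.list(f$params$constants), n = f$n, rss = f$rss,
           objective = f$objective)
    else if (inherits(f, "model_params"))
      list(model_id = f$model_id, context = f$context,
           constants = as.list(f$constants))
    else stopf("write_params expects sl_fit or model_params objects")
  }
  if (inherits(fits, c("sl_fit", "model_params"))) fits <- list(fits)
  jsonlite::write_json(lapply(fits, one), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter file
#'
#' @param path a file written by [write_params].
#' @return list of [model_params].
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(r)
    model_params(r$model_id, unlist(r$constants),
                 context = if (is.null(r$context)) "" else r$context))
}

#' Write / read speed profiles
#'
#' JSON serialization of a [fit_speed_profiles] result: per speed label the
#' adaptive-model constants plus the stored mean stride frequency and mean
#' acceleration-magnitude range.
#'
#' @param profiles a `speed_profiles` object.
#' @param path file path.
#' @return `write_profiles` invisibly returns `path`; `read_profiles`
#'   returns a `speed_profiles` object.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "speed_profiles"))
  out <- lapply(profiles, function(p)
    list(speed_label = p$speed_label,
         constants = as.list(p$params$constants),
         mean_F = p$mean_F, mean_a_r = p$mean_a_r, n = p$n))
  jsonlite::write_json(list(subject_id = attr(profiles, "subject_id"),
                            profiles = out),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  raw <- jsonlite::read_json(path)
  profiles <- lapply(raw$profiles, function(p)
    list(speed_label = p$speed_label,
         params = model_params("proposed", unlist(p$constants),
                               context = sprintf("speed=%s", p$speed_label)),
         mean_F = p$mean_F, mean_a_r = p$mean_a_r, n = p$n))
  structure(profiles, class = "speed_profiles", subject_id = raw$subject_id)
}

## every CLI run writes one of these next to its outputs
write_manifest <- function(path, config) {
  config$package_version <- as.character(utils::packageVersion("gaitlen"))
  config$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  config$config_hash <- substr(digest_config(config), 1L, 12L)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## tiny order-independent config fingerprint (no external digest package):
## sum of character codes of the serialized key=value pairs, hex-encoded
digest_config <- function(config) {
  config$config_hash <- NULL
  s <- paste(sort(paste(names(config),
                        vapply(config, function(v)
                          paste(format(v), collapse = ","), character(1)),
                        sep = "=")), collapse = ";")
  codes <- utf8ToInt(s)
  acc <- 0
  for (c in codes) acc <- (acc * 31 + c) %% 2^48
  sprintf("%06x%06x", as.integer(acc %/% 2^24), as.integer(acc %% 2^24))
}
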