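# Domain types and I/O for raw inertial streams, plus multi-sensor
# synchronization onto a common receiver-side time grid.

#' Construct a single IMU sample
#'
#' One time-stamped reading of a tri-axial accelerometer (m/s^2) and gyroscope
#' (deg/s) in the sensor's own frame.
#'
#' @param sensor_id One of `"S1"`, `"S2"`, `"S3"` (wrist joint, hand segment,
#'   forearm segment respectively).
#' @param t Receiver-assigned timestamp in seconds, non-negative.
#' @param accel Numeric length-3 acceleration in m/s^2 (includes gravity).
#' @param gyro Numeric length-3 angular velocity in deg/s.
#' @return A list of class `imu_sample`.
#' @export
imu_sample <- function(sensor_id, t, accel, gyro) {
  sensor_id <- match.arg(sensor_id, SENSOR_IDS)
  stopifnot_finite(t, "timestamp")
  if (length(t) != 1L || t < 0) vw_validation_error("timestamp must be a single value >= 0")
  if (length(accel) != 3L || length(gyro) != 3L)
    vw_validation_error("accel and gyro must each have 3 components")
  stopifnot_finite(accel, "accel")
  stopifnot_finite(gyro, "gyro")
  structure(list(sensor_id = sensor_id, t = as.numeric(t),
                 accel = as.numeric(accel), gyro = as.numeric(gyro)),
            class = "imu_sample")
}

#' Parse one sensor line of the session CSV dialect
#'
#' A line holds 8 comma-separated fields:
#' `sensor_id,t,ax,ay,az,gx,gy,gz` with accelerations in m/s^2 and gyro rates
#' in deg/s.
#'
#' @param line A single character string.
#' @param line_no Optional line number used in error messages.
#' @return An [imu_sample()].
#' @export
parse_sensor_line <- function(line, line_no = NA_integer_) {
  where <- if (is.na(line_no)) "" else sprintf(" at line %d", line_no)
  fields <- strsplit(trimws(line), ",", fixed = TRUE)[[1]]
  if (length(fields) != 8L)
    vw_parse_error(sprintf("expected 8 comma-separated fields%s, got %d",
                           where, length(fields)))
  if (!fields[1] %in% SENSOR_IDS)
    vw_parse_error(sprintf("unknown sensor id '%s'%s", fields[1], where))
  vals <- suppressWarnings(as.numeric(fields[2:8]))
  if (anyNA(vals) || any(!is.finite(vals)))
    vw_validation_error(sprintf("non-finite or unparseable numeric field%s", where))
  imu_sample(fields[1], vals[1], vals[2:4], vals[5:7])
}

#' Construct a validated IMU stream
#'
#' @param sensor_id Sensor label, one of `"S1"`, `"S2"`, `"S3"`.
#' @param t Strictly increasing timestamps in seconds.
#' @param accel n-by-3 matrix (or data frame) of accelerations, m/s^2.
#' @param gyro n-by-3 matrix of gyro rates, deg/s.
#' @param nominal_rate Nominal sampling rate in Hz (default 50).
#' @return A data frame with columns `t, ax, ay, az, gx, gy, gz` and class
#'   `imu_stream`; sensor id and nominal rate are carried as attributes.
#' @export
imu_stream <- function(sensor_id, t, accel, gyro, nominal_rate = 50) {
  sensor_id <- match.arg(sensor_id, SENSOR_IDS)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- length(t)
  if (n == 0L) vw_validation_error("stream must contain at least one sample")
  if (nrow(accel) != n || nrow(gyro) != n || ncol(accel) != 3L || ncol(gyro) != 3L)
    vw_validation_error("accel and gyro must be n-by-3 with n = length(t)")
  stopifnot_finite(t, "timestamps")
  stopifnot_finite(c(accel), "accel")
  stopifnot_finite(c(gyro), "gyro")
  if (any(t < 0)) vw_validation_error("timestamps must be non-negative")
  if (n > 1L && any(diff(t) <= 0))
    vw_validation_error(sprintf("timestamps of %s must be strictly increasing", sensor_id))
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L || nominal_rate <= 0)
    vw_validation_error("nominal_rate must be a single value > 0")
  out <- data.frame(t = as.numeric(t),
                    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3])
  rownames(out) <- NULL
  structure(out, sensor_id = sensor_id, nominal_rate = nominal_rate,
            class = c("imu_stream", "data.frame"))
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream %s: %d samples, %.6g-%.6g s, nominal %g Hz>\n",
              attr(x, "sensor_id"), nrow(x), x$t[1], x$t[nrow(x)],
              attr(x, "nominal_rate")))
  invisible(x)
}

stream_accel <- function(stream) as.matrix(stream[, c("ax", "ay", "az")])
stream_gyro  <- function(stream) as.matrix(stream[, c("gx", "gy", "gz")])
stream_id    <- function(stream) attr(stream, "sensor_id")

#' Construct a three-sensor session recording
#'
#' @param streams List of three [imu_stream()]s with distinct sensor ids
#'   covering S1, S2 and S3 (any order).
#' @param placement An [arm_model()] describing segment lengths and sensor
#'   placements.
#' @param metadata Optional named list (operator id, scenario label, ...).
#' @return A list of class `imu_session` with elements `streams` (named
#'   `S1`,`S2`,`S3`), `placement`, `metadata`.
#' @export
imu_session <- function(streams, placement = arm_model(), metadata = list()) {
  ids <- vapply(streams, stream_id, character(1))
  if (length(streams) != 3L || anyDuplicated(ids) || !setequal(ids, SENSOR_IDS))
    vw_structural_error("a session needs exactly three streams with sensor ids S1, S2, S3")
  streams <- streams[order(match(ids, SENSOR_IDS))]
  names(streams) <- SENSOR_IDS
  structure(list(streams = streams, placement = placement, metadata = metadata),
            class = "imu_session")
}

#' @export
print.imu_session <- function(x, ...) {
  cat("<imu_session>\n")
  for (s in x$streams) print(s)
  invisible(x)
}

SESSION_HEADER <- "sensor_id,t,ax,ay,az,gx,gy,gz"

#' Read / write a session in the 8-column CSV dialect
#'
#' The file holds a header row `sensor_id,t,ax,ay,az,gx,gy,gz` followed by one
#' line per sample. Values are written at full double precision so that
#' `write_session()` followed by `read_session()` round-trips a session
#' bit-exactly.
#'
#' @param path File path.
#' @param placement,metadata Passed through to [imu_session()] on read (the
#'   CSV stores samples only).
#' @param nominal_rate Nominal rate attached to the parsed streams.
#' @return `read_session()` returns an [imu_session()]; `write_session()`
#'   returns `path` invisibly.
#' @export
read_session <- function(path, placement = arm_model(), metadata = list(),
                         nominal_rate = 50) {
  if (!file.exists(path)) vw_structural_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) vw_structural_error(sprintf("empty session file: %s", path))
  if (trimws(lines[1]) != SESSION_HEADER)
    vw_structural_error(sprintf("missing or malformed header (expected '%s')", SESSION_HEADER))
  body <- lines[-1]
  if (length(body) == 0L) vw_structural_error("session file has a header but no samples")
  samples <- lapply(seq_along(body), function(i) parse_sensor_line(body[i], i + 1L))
  ids <- vapply(samples, function(s) s$sensor_id, character(1))
  missing <- setdiff(SENSOR_IDS, unique(ids))
  if (length(missing))
    vw_structural_error(sprintf("session is missing sensor stream(s): %s",
                                paste(missing, collapse = ", ")))
  streams <- lapply(SENSOR_IDS, function(id) {
    sub <- samples[ids == id]
    imu_stream(id,
               t = vapply(sub, function(s) s$t, numeric(1)),
               accel = do.call(rbind, lapply(sub, function(s) s$accel)),
               gyro = do.call(rbind, lapply(sub, function(s) s$gyro)),
               nominal_rate = nominal_rate)
  })
  imu_session(streams, placement = placement, metadata = metadata)
}

#' @rdname read_session
#' @param session An [imu_session()].
#' @export
write_session <- function(session, path) {
  if (!inherits(session, "imu_session")) vw_validation_error("not an imu_session")
  fmt <- function(x) sprintf("%.17g", x)
  chunks <- lapply(session$streams, function(s) {
    paste(stream_id(s), fmt(s$t), fmt(s$ax), fmt(s$ay), fmt(s$az),
          fmt(s$gx), fmt(s$gy), fmt(s$gz), sep = ",")
  })
  writeLines(c(SESSION_HEADER, unlist(chunks, use.names = FALSE)), path)
  invisible(path)
}

#' Synchronize three sensor streams onto a common time grid
#'
#' Emulates the receiver's round-robin polling: output frames sit on an exact
#' arithmetic grid with step `1/rate` spanning the overlap of the three
#' streams, and each frame takes the nearest sample of each sensor. Frames for
#' which any sensor's nearest sample is further than `max_skew` away are
#' dropped (and counted).
#'
#' @param streams An [imu_session()] or a list of three [imu_stream()]s.
#' @param rate Frame rate in Hz; defaults to the first stream's nominal rate.
#' @param max_skew Largest tolerated |sample time - frame time| in seconds;
#'   defaults to half a frame period (one round-robin polling cycle bounds the
#'   skew at 50 Hz).
#' @return A list of class `synced_session`: `t` (frame times), `streams`
#'   (resampled `imu_stream`s on the frame grid), `dropped` (frame count),
#'   `rate`, `max_skew`.
#' @export
round_robin_sync <- function(streams, rate = NULL, max_skew = NULL) {
  if (inherits(streams, "imu_session")) streams <- streams$streams
  ids <- vapply(streams, stream_id, character(1))
  if (length(streams) != 3L || !setequal(ids, SENSOR_IDS))
    vw_structural_error("round_robin_sync needs streams for S1, S2 and S3")
  streams <- streams[order(match(ids, SENSOR_IDS))]
  names(streams) <- SENSOR_IDS
  rate <- rate %||% attr(streams[[1]], "nominal_rate")
  if (!is.numeric(rate) || rate <= 0) vw_validation_error("rate must be > 0")
  max_skew <- max_skew %||% (0.5 / rate)

  t0 <- max(vapply(streams, function(s) s$t[1], numeric(1)))
  t1 <- min(vapply(streams, function(s) s$t[nrow(s)], numeric(1)))
  if (t1 <= t0) vw_validation_error("streams have no common time interval")
  n <- floor((t1 - t0) * rate + 1e-9) + 1L
  if (n < 2L) vw_validation_error("overlap interval yields fewer than 2 frames")
  grid <- t0 + (seq_len(n) - 1L) / rate  # bit-stable arithmetic progression

  nearest <- function(ts, grid) {
    lo <- findInterval(grid, ts, all.inside = TRUE)
    hi <- pmin(lo + 1L, length(ts))
    ifelse(abs(ts[hi] - grid) < abs(grid - ts[lo]), hi, lo)
  }
  idx <- lapply(streams, function(s) nearest(s$t, grid))
  skew <- mapply(function(s, i) abs(s$t[i] - grid), streams, idx)
  keep <- rowSums(skew > max_skew + 1e-12) == 0L
  if (sum(keep) < 2L) vw_validation_error("fewer than 2 frames survive the skew limit")

  synced <- mapply(function(s, i) {
    imu_stream(stream_id(s), t = grid[keep],
               accel = stream_accel(s)[i[keep], , drop = FALSE],
               gyro = stream_gyro(s)[i[keep], , drop = FALSE],
               nominal_rate = rate)
  }, streams, idx, SIMPLIFY = FALSE)
  structure(list(t = grid[keep], streams = synced,
                 dropped = as.integer(n - sum(keep)),
                 rate = rate, max_skew = max_skew),
            class = "synced_session")
}

#' @export
print.synced_session <- function(x, ...) {
  cat(sprintf("<synced_session: %d frames at %g Hz, %d dropped>\n",
              length(x$t), x$rate, x$dropped))
  invisible(x)
}
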