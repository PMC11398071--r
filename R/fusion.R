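# Per-sensor orientation and motion estimation: gyro integration,
# accelerometer tilt, complementary/Kalman fusion, gravity removal and
# dead-reckoning velocity/position with optional zero-velocity updates.

#' Orientation filter configuration
#'
#' @param method `"complementary"` (default), `"kalman"`, or `"gyro_only"`.
#' @param alpha Complementary weight on the gyro-propagated angle, in
#'   \[0, 1\]. 0.98 at 50 Hz gives a ~1 s accelerometer time constant.
#' @param q_angle,q_bias Kalman process-noise variances of the angle and the
#'   gyro-bias states (deg^2 per step scale).
#' @param r_measure Kalman measurement-noise variance of the accelerometer
#'   tilt angle (deg^2).
#' @param gravity_mag Gravity magnitude in m/s^2.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(method = c("complementary", "kalman", "gyro_only"),
                          alpha = 0.98, q_angle = 0.001, q_bias = 0.003,
                          r_measure = 0.03, gravity_mag = 9.81) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    vw_validation_error("alpha must lie in [0, 1]")
  if (any(c(q_angle, q_bias, r_measure) <= 0) || gravity_mag <= 0)
    vw_validation_error("noise variances and gravity_mag must be > 0")
  structure(list(method = method, alpha = alpha, q_angle = q_angle,
                 q_bias = q_bias, r_measure = r_measure,
                 gravity_mag = gravity_mag),
            class = "filter_config")
}

orientation_series <- function(t, theta, gimbal = NULL) {
  theta <- as.matrix(theta)
  gimbal <- gimbal %||% (gimbal_distance(theta[, 2]) < 1)
  structure(data.frame(t = t, x = theta[, 1], y = theta[, 2], z = theta[, 3],
                       gimbal = gimbal),
            class = c("orientation_series", "data.frame"))
}

euler_matrix <- function(os) as.matrix(os[, c("x", "y", "z")])

#' Integrate gyroscope rates into an orientation series
#'
#' Propagates per-axis Euler angles by trapezoidal integration of the gyro
#' channels, `theta(t) = theta(t-1) + integral of omega dt`. Entries whose
#' pitch comes within 1 degree of the +-90 degree singularity are flagged in
#' the `gimbal` column.
#'
#' @param stream An [imu_stream()] (gyro in deg/s).
#' @param initial_euler Starting angles in degrees (default zero).
#' @return An `orientation_series` data frame with columns
#'   `t, x, y, z, gimbal`, angles in degrees.
#' @export
integrate_gyro <- function(stream, initial_euler = c(0, 0, 0)) {
  stopifnot_finite(initial_euler, "initial_euler")
  t <- stream$t
  if (length(t) > 1L && any(diff(t) <= 0)) vw_validation_error("non-positive time step")
  g <- stream_gyro(stream)
  theta <- sapply(1:3, function(k) initial_euler[k] + cumtrapz1(t, g[, k]))
  if (length(t) == 1L) theta <- matrix(theta, nrow = 1)
  orientation_series(t, theta)
}

#' Roll/pitch from a quasi-static accelerometer reading
#'
#' Inverts the gravity direction in the sensor frame under the fixed-axis
#' X-then-Y-then-Z convention: for a static sensor the measured specific force
#' is `R(theta)' (0, 0, g)`. Yaw is unobservable from gravity; when the
#' current yaw estimate is known (e.g. gyro-integrated) it can be supplied so
#' the roll/pitch inversion stays exact for postures with nonzero yaw.
#'
#' @param accel Length-3 acceleration in m/s^2, or an [imu_sample()].
#' @param gravity_mag Gravity magnitude, m/s^2.
#' @param yaw_deg Assumed yaw angle in degrees (default 0).
#' @return Named vector `c(x = roll, y = pitch)` in degrees, or `NULL` when
#'   the acceleration magnitude is outside +-30% of `gravity_mag` (dynamic
#'   motion: no tilt estimate).
#' @export
accel_tilt <- function(accel, gravity_mag = 9.81, yaw_deg = 0) {
  if (inherits(accel, "imu_sample")) accel <- accel$accel
  stopifnot_finite(accel, "accel")
  nrm <- sqrt(sum(accel^2))
  if (abs(nrm - gravity_mag) > 0.3 * gravity_mag) return(NULL)
  a <- rot3_z(yaw_deg) %*% accel  # undo the yaw share of the sensor rotation
  roll <- asin(max(-1, min(1, a[2] / nrm)))
  pitch <- atan2(-a[1], a[3])
  c(x = rad2deg(roll), y = rad2deg(pitch))
}

#' Fuse gyroscope and accelerometer data into an orientation estimate
#'
#' Three estimators behind one interface:
#' * `complementary`: per sample, roll/pitch are
#'   `alpha * (previous + gyro step) + (1 - alpha) * accelerometer tilt`
#'   whenever the sample is quasi-static; yaw is gyro-integrated only.
#' * `kalman`: decoupled 1-D angle+bias Kalman filters on roll and pitch with
#'   gyro propagation as process model and accelerometer tilt as measurement;
#'   yaw gyro-only.
#' * `gyro_only`: identical to [integrate_gyro()].
#'
#' Unless `initial_euler` is given, roll/pitch start from the first
#' quasi-static tilt estimate (yaw starts at zero: it is re-zeroed at every
#' session start since no magnetometer exists).
#'
#' @inheritParams integrate_gyro
#' @param config A [filter_config()].
#' @return An `orientation_series` in degrees.
#' @export
fuse_orientation <- function(stream, config = filter_config(),
                             initial_euler = NULL) {
  if (config$method == "gyro_only")
    return(integrate_gyro(stream, initial_euler %||% c(0, 0, 0)))
  t <- stream$t
  if (length(t) > 1L && any(diff(t) <= 0)) vw_validation_error("non-positive time step")
  acc <- stream_accel(stream)
  gyr <- stream_gyro(stream)
  n <- length(t)
  theta <- matrix(0, n, 3)

  if (is.null(initial_euler)) {
    tilt0 <- accel_tilt(acc[1, ], config$gravity_mag, yaw_deg = 0)
    theta[1, ] <- if (is.null(tilt0)) c(0, 0, 0) else c(tilt0, 0)
  } else {
    stopifnot_finite(initial_euler, "initial_euler")
    theta[1, ] <- initial_euler
  }

  if (config$method == "complementary") {
    a <- config$alpha
    for (i in seq_len(n)[-1]) {
      dt <- t[i] - t[i - 1]
      pred <- theta[i - 1, ] + 0.5 * (gyr[i - 1, ] + gyr[i, ]) * dt
      tilt <- accel_tilt(acc[i, ], config$gravity_mag, yaw_deg = pred[3])
      theta[i, ] <- if (is.null(tilt)) pred
                    else c(a * pred[1:2] + (1 - a) * tilt, pred[3])
    }
  } else {  # kalman: decoupled angle+bias filters on roll (1) and pitch (2)
    bias <- c(0, 0)
    P <- list(diag(c(1, 0.1)), diag(c(1, 0.1)))
    for (i in seq_len(n)[-1]) {
      dt <- t[i] - t[i - 1]
      rate <- 0.5 * (gyr[i - 1, ] + gyr[i, ])
      pred <- theta[i - 1, 1:2] + (rate[1:2] - bias) * dt
      for (k in 1:2) {
        Pk <- P[[k]]
        Pk[1, 1] <- Pk[1, 1] + dt * (dt * Pk[2, 2] - Pk[1, 2] - Pk[2, 1] + config$q_angle)
        Pk[1, 2] <- Pk[1, 2] - dt * Pk[2, 2]
        Pk[2, 1] <- Pk[2, 1] - dt * Pk[2, 2]
        Pk[2, 2] <- Pk[2, 2] + config$q_bias * dt
        P[[k]] <- Pk
      }
      yaw <- theta[i - 1, 3] + rate[3] * dt
      tilt <- accel_tilt(acc[i, ], config$gravity_mag, yaw_deg = yaw)
      if (!is.null(tilt)) {
        for (k in 1:2) {
          Pk <- P[[k]]
          S <- Pk[1, 1] + config$r_measure
          K <- c(Pk[1, 1], Pk[2, 1]) / S
          innov <- tilt[k] - pred[k]
          pred[k] <- pred[k] + K[1] * innov
          bias[k] <- bias[k] + K[2] * innov
          Pk <- Pk - K %*% t(c(Pk[1, 1], Pk[1, 2]))
          P[[k]] <- Pk
        }
      }
      theta[i, ] <- c(pred, yaw)
    }
  }
  orientation_series(t, theta)
}

#' Remove gravity from an accelerometer reading
#'
#' `a_real = a_measured - R(euler)' (0, 0, g)`: the world gravity vector is
#' rotated into the sensor frame by the current orientation estimate and
#' subtracted. A static, correctly oriented sample yields ~0.
#'
#' @param accel Length-3 measured acceleration (m/s^2) or an [imu_sample()].
#' @param euler_deg Length-3 orientation estimate in degrees.
#' @param gravity_mag Gravity magnitude, m/s^2.
#' @return Length-3 linear acceleration in the sensor frame, m/s^2.
#' @export
remove_gravity <- function(accel, euler_deg, gravity_mag = 9.81) {
  if (inherits(accel, "imu_sample")) accel <- accel$accel
  stopifnot_finite(accel, "accel")
  stopifnot_finite(euler_deg, "euler_deg")
  as.numeric(accel - t(rot3_xyz(euler_deg)) %*% c(0, 0, gravity_mag))
}

#' Gravity-free acceleration for a whole stream
#'
#' @param stream An [imu_stream()].
#' @param orientation An `orientation_series` on the same time base.
#' @param gravity_mag Gravity magnitude, m/s^2.
#' @return Data frame `t, ax, ay, az` of linear (gravity-free) acceleration.
#' @export
linear_acceleration <- function(stream, orientation, gravity_mag = 9.81) {
  if (nrow(stream) != nrow(orientation) ||
      max(abs(stream$t - orientation$t)) > 1e-9)
    vw_validation_error("stream and orientation series are on different time bases")
  acc <- stream_accel(stream)
  eul <- euler_matrix(orientation)
  lin <- t(vapply(seq_len(nrow(acc)),
                  function(i) remove_gravity(acc[i, ], eul[i, ], gravity_mag),
                  numeric(3)))
  data.frame(t = stream$t, ax = lin[, 1], ay = lin[, 2], az = lin[, 3])
}

#' Detect rest windows on a raw stream
#'
#' A sample is at rest when the gyro magnitude is below `gyro_thresh` and the
#' acceleration magnitude is within `accel_thresh` of gravity; runs shorter
#' than `min_duration` are discarded.
#'
#' @param stream An [imu_stream()].
#' @param gyro_thresh deg/s (default 2).
#' @param accel_thresh m/s^2 (default 0.3).
#' @param min_duration seconds (default 0.2).
#' @param gravity_mag m/s^2.
#' @return Data frame with columns `start`, `end` (seconds).
#' @export
detect_rest_windows <- function(stream, gyro_thresh = 2, accel_thresh = 0.3,
                                min_duration = 0.2, gravity_mag = 9.81) {
  gmag <- sqrt(rowSums(stream_gyro(stream)^2))
  amag <- sqrt(rowSums(stream_accel(stream)^2))
  still <- gmag < gyro_thresh & abs(amag - gravity_mag) < accel_thresh
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (stream$t[ends] - stream$t[starts]) >= min_duration
  data.frame(start = stream$t[starts[keep]], end = stream$t[ends[keep]])
}

#' Dead-reckon velocity and position from linear acceleration
#'
#' Trapezoidal integration of gravity-free acceleration into velocity and of
#' velocity into position. When `rest_windows` are supplied, velocity is reset
#' to zero inside each window (zero-velocity update), which bounds the
#' otherwise cubically growing position drift.
#'
#' @param lin Data frame `t, ax, ay, az` as returned by
#'   [linear_acceleration()].
#' @param initial_velocity,initial_position Length-3 starting states (m/s, m).
#' @param rest_windows Optional data frame `start, end` (e.g. from
#'   [detect_rest_windows()]).
#' @return A data frame of class `motion_state` with columns
#'   `t, ax..az, vx..vz, px..pz`.
#' @export
integrate_motion <- function(lin, initial_velocity = c(0, 0, 0),
                             initial_position = c(0, 0, 0),
                             rest_windows = NULL) {
  t <- lin$t
  if (length(t) > 1L && any(diff(t) <= 0)) vw_validation_error("non-positive time step")
  a <- as.matrix(lin[, c("ax", "ay", "az")])
  v <- sapply(1:3, function(k) initial_velocity[k] + cumtrapz1(t, a[, k]))
  if (!is.null(rest_windows) && nrow(rest_windows)) {
    at_rest <- rep(FALSE, length(t))
    for (i in seq_len(nrow(rest_windows)))
      at_rest <- at_rest | (t >= rest_windows$start[i] & t <= rest_windows$end[i])
    # re-integrate piecewise: v is pinned to 0 through rests
    for (k in 1:3) {
      vk <- initial_velocity[k] + cumtrapz1(t, a[, k])
      corr <- numeric(length(t))
      offset <- 0
      for (i in seq_along(t)) {
        if (at_rest[i]) offset <- vk[i]
        corr[i] <- vk[i] - offset
      }
      v[, k] <- corr
    }
  }
  p <- sapply(1:3, function(k) initial_position[k] + cumtrapz1(t, v[, k]))
  out <- data.frame(t = t, ax = a[, 1], ay = a[, 2], az = a[, 3],
                    vx = v[, 1], vy = v[, 2], vz = v[, 3],
                    px = p[, 1], py = p[, 2], pz = p[, 3])
  structure(out, class = c("motion_state", "data.frame"))
}
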