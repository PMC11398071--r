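# Synthetic-data generator: ground-truth wrist trajectories (smoothstep
# keyframe interpolation with analytic rates) and the three consistent noisy
# IMU streams they imply, emulating the laboratory reference-angle protocol
# and the simulated-vine pruning protocol.

#' Keyframe trajectory specification
#'
#' Wrist Euler angles move between keyframes along a smoothstep
#' (`3u^2 - 2u^3`) profile, so the trajectory is C1 and its angular rate is
#' known analytically.
#'
#' @param keyframes Data frame with columns `t` (seconds, strictly
#'   increasing) and `x`, `y`, `z` (degrees).
#' @param rate Sampling rate in Hz (default 50).
#' @return A list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(keyframes, rate = 50) {
  need <- c("t", "x", "y", "z")
  if (!is.data.frame(keyframes) || !all(need %in% names(keyframes)))
    vw_validation_error("keyframes need columns t, x, y, z")
  if (nrow(keyframes) < 1L || (nrow(keyframes) > 1L && any(diff(keyframes$t) <= 0)))
    vw_validation_error("keyframe times must be strictly increasing")
  if (rate <= 0) vw_validation_error("rate must be > 0")
  structure(list(keyframes = keyframes[, need], rate = rate),
            class = "trajectory_spec")
}

#' Inertial noise model
#'
#' @param accel_sigma Accelerometer white-noise SD in m/s^2 (default 0.05).
#' @param gyro_sigma Gyro white-noise SD in deg/s (default 0.5).
#' @param gyro_bias Constant gyro bias per axis in deg/s (default zero).
#' @param seed RNG seed; identical seeds give bit-identical sessions.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(accel_sigma = 0.05, gyro_sigma = 0.5,
                        gyro_bias = c(0, 0, 0), seed = 20240902) {
  if (accel_sigma < 0 || gyro_sigma < 0)
    vw_validation_error("noise sigmas must be >= 0")
  if (length(gyro_bias) == 1L) gyro_bias <- rep(gyro_bias, 3)
  structure(list(accel_sigma = accel_sigma, gyro_sigma = gyro_sigma,
                 gyro_bias = gyro_bias, seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free model (all sigmas and biases zero)
#'
#' @param seed RNG seed (unused when all sigmas are zero, kept for symmetry).
#' @return A [noise_model()] with zero noise.
#' @export
noise_free <- function(seed = 20240902) {
  noise_model(accel_sigma = 0, gyro_sigma = 0, gyro_bias = c(0, 0, 0),
              seed = seed)
}

# value and analytic rate of the smoothstep interpolant at times t
smoothstep_series <- function(kf_t, kf_v, t) {
  i <- findInterval(t, kf_t)
  val <- numeric(length(t)); rate <- numeric(length(t))
  val[i == 0] <- kf_v[1]
  val[i >= length(kf_t)] <- kf_v[length(kf_v)]
  mid <- i > 0 & i < length(kf_t)
  if (any(mid)) {
    i0 <- i[mid]
    dt <- kf_t[i0 + 1] - kf_t[i0]
    u <- (t[mid] - kf_t[i0]) / dt
    dv <- kf_v[i0 + 1] - kf_v[i0]
    val[mid] <- kf_v[i0] + dv * u * u * (3 - 2 * u)
    rate[mid] <- dv * 6 * u * (1 - u) / dt
  }
  list(value = val, rate = rate)
}

# summed raised-cosine burst magnitudes at times t; bursts: center, amplitude,
# duration
burst_profile <- function(t, bursts) {
  b <- numeric(length(t))
  if (is.null(bursts) || nrow(bursts) == 0L) return(b)
  for (j in seq_len(nrow(bursts))) {
    s <- bursts$center[j] - bursts$duration[j] / 2
    sel <- t >= s & t <= s + bursts$duration[j]
    b[sel] <- b[sel] + bursts$amplitude[j] * 0.5 *
      (1 - cos(2 * pi * (t[sel] - s) / bursts$duration[j]))
  }
  b
}

#' Evaluate a ground-truth trajectory on the sampling grid
#'
#' @param spec A [trajectory_spec()] for the hand segment.
#' @param forearm_spec Optional [trajectory_spec()] for the forearm; held at
#'   zero when absent.
#' @param bursts Optional data frame `center, amplitude, duration` of
#'   world-vertical raised-cosine linear-acceleration pulses (cut bursts).
#' @return A list of class `synth_truth`: `t`, `hand`/`forearm` (n-by-3 Euler
#'   degrees), `hand_rate`/`forearm_rate` (deg/s, analytic), `lin_accel_mag`
#'   (m/s^2, world-vertical), `bursts`, `rate`.
#' @export
generate_trajectory <- function(spec, forearm_spec = NULL, bursts = NULL) {
  kf <- spec$keyframes
  t0 <- kf$t[1]; t1 <- kf$t[nrow(kf)]
  n <- if (t1 > t0) floor((t1 - t0) * spec$rate + 1e-9) + 1L else 1L
  t <- t0 + (seq_len(n) - 1L) / spec$rate
  ax <- lapply(c("x", "y", "z"), function(a) smoothstep_series(kf$t, kf[[a]], t))
  hand <- cbind(ax[[1]]$value, ax[[2]]$value, ax[[3]]$value)
  hand_rate <- cbind(ax[[1]]$rate, ax[[2]]$rate, ax[[3]]$rate)
  if (is.null(forearm_spec)) {
    forearm <- matrix(0, n, 3); forearm_rate <- matrix(0, n, 3)
  } else {
    fk <- forearm_spec$keyframes
    fx <- lapply(c("x", "y", "z"), function(a) smoothstep_series(fk$t, fk[[a]], t))
    forearm <- cbind(fx[[1]]$value, fx[[2]]$value, fx[[3]]$value)
    forearm_rate <- cbind(fx[[1]]$rate, fx[[2]]$rate, fx[[3]]$rate)
  }
  structure(list(t = t, hand = hand, hand_rate = hand_rate,
                 forearm = forearm, forearm_rate = forearm_rate,
                 lin_accel_mag = burst_profile(t, bursts),
                 bursts = bursts, rate = spec$rate),
            class = "synth_truth")
}

#' Synthesize a three-sensor IMU session from a ground-truth trajectory
#'
#' Inverts the estimation model: per sensor, the gyro channels are the
#' segment's analytic Euler-angle rates plus bias and Gaussian noise, and the
#' accelerometer reads the world gravity-plus-burst vector rotated into the
#' sensor frame plus Gaussian noise. S2 co-moves with the hand segment and
#' carries the full cut burst; S1 (wrist axis) and S3 (forearm) co-move with
#' the forearm segment and receive attenuated shares of the burst.
#'
#' @param truth A `synth_truth` from [generate_trajectory()].
#' @param placement An [arm_model()].
#' @param noise A [noise_model()]; sessions are bit-reproducible given the
#'   seed.
#' @param gravity_mag Gravity magnitude in m/s^2.
#' @param burst_gains Named burst attenuation per sensor.
#' @param metadata Metadata list stored in the session.
#' @return An [imu_session()].
#' @export
synthesize_imu <- function(truth, placement = arm_model(),
                           noise = noise_model(), gravity_mag = 9.81,
                           burst_gains = c(S1 = 0.5, S2 = 1, S3 = 0.1),
                           metadata = list()) {
  n <- length(truth$t)
  segment <- list(S1 = "forearm", S2 = "hand", S3 = "forearm")
  streams <- with_seed(noise$seed, lapply(SENSOR_IDS, function(id) {
    eul <- truth[[segment[[id]]]]
    rate <- truth[[paste0(segment[[id]], "_rate")]]
    vert <- gravity_mag + burst_gains[[id]] * truth$lin_accel_mag
    accel <- t(vapply(seq_len(n),
                      function(i) vert[i] * rot3_xyz(eul[i, ])[3, ],
                      numeric(3)))
    gyro <- rate + matrix(rep(noise$gyro_bias, each = n), n, 3)
    if (noise$gyro_sigma > 0)
      gyro <- gyro + matrix(stats::rnorm(3 * n, sd = noise$gyro_sigma), n, 3)
    if (noise$accel_sigma > 0)
      accel <- accel + matrix(stats::rnorm(3 * n, sd = noise$accel_sigma), n, 3)
    imu_stream(id, truth$t, accel, gyro, nominal_rate = truth$rate)
  }))
  imu_session(streams, placement = placement, metadata = metadata)
}

#' Synthesize a laboratory reference-angle trial
#'
#' Emulates the validation protocol: from neutral, ramp to the target posture
#' on one axis, hold, return, rest - repeated `reps` times (three in the
#' laboratory protocol).
#'
#' @param angle Target angle in degrees, one of 15, 45, 60 for the
#'   laboratory protocol (other values are allowed for exploration).
#' @param axis `"X"`, `"Y"` or `"Z"`.
#' @param noise A [noise_model()].
#' @param reps Number of repetitions (default 3).
#' @param rate Sampling rate, Hz.
#' @param ramp,hold,rest Phase durations in seconds.
#' @param placement An [arm_model()].
#' @return List of class `reference_trial_synth`: `session`, `truth`,
#'   `target_angle`, `axis`, `hold_windows` (data frame `rep, start, end`,
#'   trimmed 0.2 s inside each hold), and session metadata carrying
#'   `repetitions`.
#' @export
generate_reference_trial <- function(angle, axis = c("X", "Y", "Z"),
                                     noise = noise_model(), reps = 3,
                                     rate = 50, ramp = 1, hold = 2, rest = 1,
                                     placement = arm_model()) {
  axis <- match.arg(axis)
  stopifnot_finite(angle, "angle")
  k <- match(axis, c("X", "Y", "Z"))
  kf <- data.frame(t = 0, x = 0, y = 0, z = 0)
  hold_windows <- NULL
  cursor <- 0
  for (r in seq_len(reps)) {
    peak <- c(0, 0, 0); peak[k] <- angle
    times <- cursor + cumsum(c(ramp, hold, ramp, rest))
    kf <- rbind(kf,
                data.frame(t = times[1], x = peak[1], y = peak[2], z = peak[3]),
                data.frame(t = times[2], x = peak[1], y = peak[2], z = peak[3]),
                data.frame(t = times[3], x = 0, y = 0, z = 0),
                data.frame(t = times[4], x = 0, y = 0, z = 0))
    hold_windows <- rbind(hold_windows,
                          data.frame(rep = r, start = times[1] + 0.2,
                                     end = times[2] - 0.2))
    cursor <- times[4]
  }
  truth <- generate_trajectory(trajectory_spec(kf, rate = rate))
  session <- synthesize_imu(truth, placement = placement, noise = noise,
                            metadata = list(scenario = "reference_trial",
                                            target_angle = angle, axis = axis,
                                            repetitions = reps))
  structure(list(session = session, truth = truth, target_angle = angle,
                 axis = axis, hold_windows = hold_windows),
            class = "reference_trial_synth")
}

#' Pruning scenario description
#'
#' The simulated-vine protocol: sequences of seven cuts, each cut reaching a
#' peak wrist posture coincident with an acceleration burst, repeated three
#' times per operator. Default per-cut peak angles sample the published
#' per-operator cut angles so the classification path can be exercised
#' end-to-end.
#'
#' @param peak_angles Optional 3-D array `[cut, axis, sequence]` of peak wrist
#'   angles in degrees; defaults to the shipped pruning fixture for
#'   `operator`.
#' @param operator Operator id 1-4 used for the default peak angles.
#' @param n_cuts,n_sequences Protocol sizes (7 and 3 for the field-protocol
#'   preset).
#' @param move,hold,rest Per-cut phase durations in seconds.
#' @param inter_sequence_rest Pause between sequences, seconds.
#' @param burst_amp Burst peak amplitude in m/s^2 (default 8).
#' @param burst_duration Burst duration in seconds (default 0.3).
#' @param rate Sampling rate, Hz.
#' @return A list of class `pruning_scenario`.
#' @export
pruning_scenario <- function(peak_angles = NULL, operator = 1, n_cuts = 7,
                             n_sequences = 3, move = 0.5, hold = 0.4,
                             rest = 1, inter_sequence_rest = 3, burst_amp = 8,
                             burst_duration = 0.3, rate = 50) {
  if (is.null(peak_angles)) {
    fx <- load_pruning_fixture()
    fx <- fx[fx$operator == operator, ]
    peak_angles <- array(NA_real_, dim = c(n_cuts, 3, n_sequences),
                         dimnames = list(NULL, c("x", "y", "z"), NULL))
    for (s in seq_len(n_sequences)) for (cc in seq_len(n_cuts)) {
      sub <- fx[fx$sequence == s & fx$cut == cc, ]
      peak_angles[cc, , s] <- sub$angle_deg[match(c("X", "Y", "Z"), sub$axis)]
    }
  }
  if (any(dim(peak_angles) != c(n_cuts, 3, n_sequences)))
    vw_validation_error("peak_angles must be [n_cuts, 3, n_sequences]")
  if (anyNA(peak_angles)) vw_validation_error("peak_angles contain NA")
  if (burst_amp <= 0 || burst_duration <= 0)
    vw_validation_error("burst amplitude and duration must be > 0")
  structure(list(peak_angles = peak_angles, operator = operator,
                 n_cuts = n_cuts, n_sequences = n_sequences, move = move,
                 hold = hold, rest = rest,
                 inter_sequence_rest = inter_sequence_rest,
                 burst_amp = burst_amp, burst_duration = burst_duration,
                 rate = rate),
            class = "pruning_scenario")
}

#' Synthesize a full pruning session
#'
#' Builds the hand-segment trajectory through every cut of every sequence
#' (burst centred in each hold phase) and the three noisy sensor streams, and
#' returns the ground-truth cut events for oracle testing.
#'
#' @param scenario A [pruning_scenario()].
#' @param noise A [noise_model()].
#' @param placement An [arm_model()].
#' @return List of class `pruning_session_synth`: `session`, `truth`,
#'   `events` (data frame `sequence, cut, center, amplitude, duration, start,
#'   end, x, y, z` - start/end are the burst support), `scenario`.
#' @export
generate_pruning_session <- function(scenario, noise = noise_model(),
                                     placement = arm_model()) {
  sc <- scenario
  kf <- data.frame(t = 0, x = 0, y = 0, z = 0)
  events <- NULL
  cursor <- 0
  for (s in seq_len(sc$n_sequences)) {
    for (cc in seq_len(sc$n_cuts)) {
      peak <- sc$peak_angles[cc, , s]
      times <- cursor + cumsum(c(sc$move, sc$hold, sc$move, sc$rest))
      kf <- rbind(kf,
                  data.frame(t = times[1], x = peak[1], y = peak[2], z = peak[3]),
                  data.frame(t = times[2], x = peak[1], y = peak[2], z = peak[3]),
                  data.frame(t = times[3], x = 0, y = 0, z = 0),
                  data.frame(t = times[4], x = 0, y = 0, z = 0))
      center <- (times[1] + times[2]) / 2
      events <- rbind(events,
                      data.frame(sequence = s, cut = cc, center = center,
                                 amplitude = sc$burst_amp,
                                 duration = sc$burst_duration,
                                 start = center - sc$burst_duration / 2,
                                 end = center + sc$burst_duration / 2,
                                 x = peak[1], y = peak[2], z = peak[3]))
      cursor <- times[4]
    }
    if (s < sc$n_sequences) {
      cursor <- cursor + sc$inter_sequence_rest
      kf <- rbind(kf, data.frame(t = cursor, x = 0, y = 0, z = 0))
    }
  }
  truth <- generate_trajectory(trajectory_spec(kf, rate = sc$rate),
                               bursts = events[, c("center", "amplitude", "duration")])
  session <- synthesize_imu(truth, placement = placement, noise = noise,
                            metadata = list(scenario = "pruning",
                                            operator = sc$operator,
                                            n_cuts = sc$n_cuts,
                                            n_sequences = sc$n_sequences))
  structure(list(session = session, truth = truth, events = events,
                 scenario = sc),
            class = "pruning_session_synth")
}

#' Analytic detection window of a ground-truth burst
#'
#' For a raised-cosine pulse of given amplitude and duration, the interval on
#' which its magnitude exceeds `threshold`; this is what an ideal threshold
#' detector should report, computed independently of the detector.
#'
#' @param events Ground-truth events from [generate_pruning_session()].
#' @param threshold Detection threshold in m/s^2.
#' @return Data frame `start, end` per event (NA when the burst never reaches
#'   the threshold).
#' @export
cut_window_truth <- function(events, threshold = 2) {
  u0 <- ifelse(threshold < events$amplitude,
               acos(1 - 2 * threshold / events$amplitude) / (2 * pi),
               NA_real_)
  data.frame(start = events$start + u0 * events$duration,
             end = events$end - u0 * events$duration)
}

#' Median wrist angle inside each hold window of a synthetic trial
#'
#' @param angles A `joint_angle_series` (see [wrist_angles()]).
#' @param trial A `reference_trial_synth`.
#' @return Data frame `rep, x, y, z` of hold-phase median angles (degrees).
#' @export
hold_phase_angles <- function(angles, trial) {
  out <- lapply(seq_len(nrow(trial$hold_windows)), function(r) {
    w <- trial$hold_windows[r, ]
    sel <- angles$t >= w$start & angles$t <= w$end
    data.frame(rep = w$rep, x = stats::median(angles$x[sel]),
               y = stats::median(angles$y[sel]),
               z = stats::median(angles$z[sel]))
  })
  do.call(rbind, out)
}
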