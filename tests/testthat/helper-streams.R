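# Builders for small in-code fixtures used across the test files.

G <- 9.81

# stream with constant accel/gyro; n = duration * rate samples starting at t0
const_stream <- function(id = "S1", duration = 2, rate = 50,
                         accel = c(0, 0, G), gyro = c(0, 0, 0), t0 = 0) {
  n <- round(duration * rate)
  t <- t0 + (seq_len(n) - 1) / rate
  imu_stream(id, t, matrix(accel, n, 3, byrow = TRUE),
             matrix(gyro, n, 3, byrow = TRUE), nominal_rate = rate)
}

static_session <- function(duration = 2, rate = 50) {
  imu_session(lapply(c("S1", "S2", "S3"), const_stream,
                     duration = duration, rate = rate))
}

# accel reading of a static sensor at the given Euler pose (degrees)
static_accel <- function(euler_deg, g = G) {
  rx <- euler_deg[1] * pi / 180; ry <- euler_deg[2] * pi / 180
  rz <- euler_deg[3] * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  as.numeric(t(Rx %*% Ry %*% Rz) %*% c(0, 0, g))
}

random_session_lines <- function(n = 100, seed = 42) {
  set.seed(seed)
  t <- cumsum(runif(n, 0.01, 0.03))
  streams <- lapply(c("S1", "S2", "S3"), function(id)
    imu_stream(id, t, matrix(rnorm(3 * n, sd = 3), n, 3),
               matrix(rnorm(3 * n, sd = 40), n, 3)))
  imu_session(streams)
}
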