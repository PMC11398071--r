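test_that("gyro integration recovers closed forms", {
  # constant rate: trapezoid is exact, theta = omega * t
  st <- const_stream(gyro = c(10, 0, 0), duration = 2.02)  # last t = 2.0
  os <- integrate_gyro(st)
  expect_equal(os$x[nrow(os)], 20, tolerance = 1e-9)
  expect_equal(os$y, rep(0, nrow(os)))
  expect_equal(os$z, rep(0, nrow(os)))

  # zero rate: orientation constant at the initial value
  os0 <- integrate_gyro(const_stream(), initial_euler = c(5, -3, 8))
  expect_equal(unique(os0$x), 5)
  expect_equal(unique(os0$z), 8)
})

test_that("trapezoid quadrature is second order on a sinusoidal rate", {
  A <- 10
  mk <- function(rate) {
    t <- seq(0, 2, by = 1 / rate)
    imu_stream("S1", t, matrix(c(0, 0, G), length(t), 3, byrow = TRUE),
               cbind(A * cos(t), 0, 0), nominal_rate = rate)
  }
  err <- function(rate) {
    os <- integrate_gyro(mk(rate))
    max(abs(os$x - A * sin(os$t)))
  }
  e50 <- err(50); e100 <- err(100)
  # analytic bound: (b-a) h^2 max|f''| / 12
  expect_lt(e50, 2 * (1 / 50)^2 * A / 12 * 1.01)
  expect_gt(e50 / e100, 3.5)
  expect_lt(e50 / e100, 4.5)
})

test_that("accelerometer tilt inverts quasi-static gravity geometry", {
  expect_equal(accel_tilt(c(0, 0, G)), c(x = 0, y = 0))
  expect_equal(accel_tilt(c(0, G * sin(pi / 4), G * cos(pi / 4))),
               c(x = 45, y = 0), tolerance = 1e-9)
  expect_null(accel_tilt(c(0, 0, 25)))  # dynamic rejection
  # pitched pose
  expect_equal(accel_tilt(static_accel(c(0, 30, 0))), c(x = 0, y = 30),
               tolerance = 1e-9)
  # yaw-compensated tilt stays exact for postures with nonzero yaw
  a <- static_accel(c(40, 20, 35))
  expect_equal(accel_tilt(a, yaw_deg = 35), c(x = 40, y = 20), tolerance = 1e-9)
})

test_that("gravity removal matches the rotated-gravity model", {
  expect_equal(remove_gravity(c(0, 0, G), c(0, 0, 0)), c(0, 0, 0))
  expect_equal(remove_gravity(static_accel(c(30, 0, 0)), c(30, 0, 0)),
               c(0, 0, 0), tolerance = 1e-12)
  expect_equal(remove_gravity(c(0, 0, 0), c(0, 0, 0)), c(0, 0, -G))
})

test_that("the subtracted gravity vector always has magnitude g", {
  set.seed(1)
  for (i in 1:200) {
    e <- runif(3, -180, 180)
    res <- remove_gravity(c(0, 0, 0), e)
    expect_equal(sqrt(sum(res^2)), G, tolerance = 1e-12)
  }
})

test_that("complementary filter with alpha = 1 degenerates to gyro integration", {
  set.seed(2)
  n <- 100
  t <- (seq_len(n) - 1) / 50
  st <- imu_stream("S2", t, matrix(rnorm(3 * n, c(0, 0, G), 0.2), n, 3),
                   matrix(rnorm(3 * n, sd = 30), n, 3))
  a <- fuse_orientation(st, filter_config(alpha = 1), initial_euler = c(0, 0, 0))
  b <- integrate_gyro(st, initial_euler = c(0, 0, 0))
  expect_equal(a$x, b$x, tolerance = 1e-12)
  expect_equal(a$y, b$y, tolerance = 1e-12)
  expect_equal(a$z, b$z, tolerance = 1e-12)
})

test_that("complementary filter converges to accelerometer tilt on static data", {
  st <- const_stream("S2", duration = 10, accel = static_accel(c(45, 0, 0)))
  # default initialization seeds roll/pitch from the first tilt estimate
  os <- fuse_orientation(st, filter_config())
  expect_lt(max(abs(os$x[os$t >= 5] - 45)), 0.1)
  # forced cold start still converges (alpha = 0.98 ~ 1 s time constant)
  cold <- fuse_orientation(st, filter_config(), initial_euler = c(0, 0, 0))
  expect_lt(abs(cold$x[nrow(cold)] - 45), 0.1)
  expect_lt(abs(cold$x[which.min(abs(cold$t - 5))] - 45), 0.5)
  # kalman variant agrees on the static fixed point
  kf <- fuse_orientation(st, filter_config(method = "kalman"),
                         initial_euler = c(0, 0, 0))
  expect_lt(abs(kf$x[nrow(kf)] - 45), 0.5)
})

test_that("constant gyro bias drifts gyro-only output but not the fused one", {
  st <- const_stream("S2", duration = 30, accel = static_accel(c(45, 0, 0)),
                     gyro = c(1, 0, 0))
  fused <- fuse_orientation(st, filter_config(), initial_euler = c(45, 0, 0))
  raw <- fuse_orientation(st, filter_config(method = "gyro_only"),
                          initial_euler = c(45, 0, 0))
  err_f <- abs(fused$x - 45)
  err_r <- abs(raw$x - 45)
  expect_lt(max(err_f), 2)                             # bounded
  expect_lt(err_f[length(err_f)] - err_f[which.min(abs(fused$t - 15))], 0.1)
  expect_equal(err_r[length(err_r)], 1 * (st$t[nrow(st)] - st$t[1]),
               tolerance = 1e-9)                       # 1 deg/s linear drift
})

test_that("motion integration recovers kinematic closed forms", {
  t <- seq(0, 2, by = 0.02)
  lin0 <- data.frame(t = t, ax = 0, ay = 0, az = 0)
  m0 <- integrate_motion(lin0)
  expect_equal(max(abs(c(m0$vx, m0$px))), 0)

  lin1 <- data.frame(t = t, ax = 1, ay = 0, az = 0)
  m1 <- integrate_motion(lin1)
  expect_equal(m1$vx[length(t)], 2, tolerance = 1e-12)
  expect_equal(m1$px[length(t)], 2, tolerance = 1e-12)
})

test_that("position noise grows cubically without ZUPT and stays bounded with it", {
  set.seed(3)
  rate <- 50
  t <- seq(0, 8, by = 1 / rate)
  p_at <- function(lin, tt, rest = NULL) {
    m <- integrate_motion(lin, rest_windows = rest)
    m$px[which.min(abs(m$t - tt))]
  }
  p4 <- p8 <- p8z <- numeric(40)
  rests <- data.frame(start = seq(0.5, 7.5, by = 1), end = seq(0.7, 7.7, by = 1))
  for (r in 1:40) {
    lin <- data.frame(t = t, ax = rnorm(length(t), sd = 0.05), ay = 0, az = 0)
    p4[r] <- p_at(lin, 4); p8[r] <- p_at(lin, 8)
    p8z[r] <- p_at(lin, 8, rest = rests)
  }
  ratio <- var(p8) / var(p4)   # random-walk scaling: variance ~ t^3 => ~8x
  expect_gt(ratio, 3)
  expect_lt(ratio, 24)
  expect_lt(var(p8z), var(p8) / 4)  # zero-velocity updates bound the drift
})

test_that("rest windows are detected from gyro and accel magnitudes", {
  still <- const_stream("S2", duration = 1)
  moving <- const_stream("S2", duration = 1, gyro = c(40, 0, 0), t0 = 1)
  still2 <- const_stream("S2", duration = 1, t0 = 2)
  st <- imu_stream("S2", c(still$t, moving$t, still2$t),
                   rbind(as.matrix(still[, 2:4]),
                         as.matrix(moving[, 2:4]), as.matrix(still2[, 2:4])),
                   rbind(as.matrix(still[, 5:7]), as.matrix(moving[, 5:7]),
                         as.matrix(still2[, 5:7])))
  w <- detect_rest_windows(st)
  expect_equal(nrow(w), 2)
  expect_lt(w$end[1], 1)
  expect_gte(w$start[2], 2)
})
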