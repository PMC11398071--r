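test_that("translation matrices behave as the homogeneous group element", {
  expect_equal(unclass(translation(0, 0, 0)), diag(4), ignore_attr = TRUE)
  expect_equal(apply_transform(translation(1, 2, 3), c(0, 0, 0)), c(1, 2, 3))
  expect_equal(unclass(translation(1, -2, 0.5) %*% translation(2, 3, 1)),
               unclass(translation(3, 1, 1.5)), ignore_attr = TRUE)
})

test_that("cardinal rotations follow the right-hand sign convention", {
  expect_equal(unclass(rotation_x(0)), diag(4), ignore_attr = TRUE)
  expect_equal(apply_transform(rotation_z(90), c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  expect_equal(apply_transform(rotation_x(90), c(0, 1, 0)), c(0, 0, 1),
               tolerance = 1e-12)
  expect_equal(apply_transform(rotation_y(90), c(0, 0, 1)), c(1, 0, 0),
               tolerance = 1e-12)
  expect_equal(unclass(rotation_x(25) %*% rotation_x(17)),
               unclass(rotation_x(42)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rototranslate composes T * Rx * Ry * Rz in that exact order", {
  expect_equal(unclass(rototranslate()), diag(4), ignore_attr = TRUE)
  expect_equal(unclass(rototranslate(1, 2, 3)), unclass(translation(1, 2, 3)),
               ignore_attr = TRUE)

  # independent brute-force oracle: assemble the four printed matrices by hand
  oracle <- function(dx, dy, dz, ax, ay, az) {
    r <- c(ax, ay, az) * pi / 180
    Tm <- rbind(c(1, 0, 0, dx), c(0, 1, 0, dy), c(0, 0, 1, dz), c(0, 0, 0, 1))
    Rx <- rbind(c(1, 0, 0, 0), c(0, cos(r[1]), -sin(r[1]), 0),
                c(0, sin(r[1]), cos(r[1]), 0), c(0, 0, 0, 1))
    Ry <- rbind(c(cos(r[2]), 0, sin(r[2]), 0), c(0, 1, 0, 0),
                c(-sin(r[2]), 0, cos(r[2]), 0), c(0, 0, 0, 1))
    Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0, 0), c(sin(r[3]), cos(r[3]), 0, 0),
                c(0, 0, 1, 0), c(0, 0, 0, 1))
    Tm %*% Rx %*% Ry %*% Rz
  }
  p <- oracle(0, 0, 0, 30, 40, 50) %*% c(0, 0, 1, 1)
  expect_equal(apply_transform(rototranslate(0, 0, 0, 30, 40, 50), c(0, 0, 1)),
               p[1:3], tolerance = 1e-12)

  set.seed(1234)
  worst <- 0
  for (i in 1:1000) {
    d <- runif(3, -2, 2); a <- runif(3, -180, 180)
    m <- rototranslate(d[1], d[2], d[3], a[1], a[2], a[3])
    worst <- max(worst, max(abs(unclass(m) - oracle(d[1], d[2], d[3],
                                                    a[1], a[2], a[3]))))
    R <- unclass(m)[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
  }
  expect_lt(worst, 1e-12)
})

test_that("forward kinematics preserves the hand-segment length", {
  model <- arm_model(len_ab = 0.18, len_ac = 0.26)
  rest <- forward_kinematics(model, c(0, 0, 0))
  expect_equal(rest$N, c(0, 0.18, 0))
  expect_equal(rest$S2, c(0, 0.09, 0))

  bent <- forward_kinematics(model, c(0, 0, 90))
  expect_equal(sqrt(sum(bent$N^2)), 0.18, tolerance = 1e-12)
  expect_lt(abs(sum(bent$N * rest$N)), 1e-12)  # perpendicular to rest pose

  set.seed(99)
  for (i in 1:1000) {
    fk <- forward_kinematics(model, runif(3, -180, 180))
    expect_equal(sqrt(sum(fk$N^2)), 0.18, tolerance = 1e-12)
    expect_equal(sqrt(sum(fk$S2^2)), 0.09, tolerance = 1e-12)
  }
})

test_that("arm model rejects non-positive segment lengths", {
  expect_error(arm_model(len_ab = 0), class = "vw_validation_error")
  expect_error(arm_model(len_ac = -1), class = "vw_validation_error")
})

test_that("relative orientation recovers the hand-vs-forearm rotation", {
  t <- (0:49) / 50
  mk <- function(x = 0, y = 0, z = 0) {
    structure(data.frame(t = t, x = x, y = y, z = z, gimbal = FALSE),
              class = c("orientation_series", "data.frame"))
  }
  same <- relative_orientation(mk(10, 5, -3), mk(10, 5, -3))
  expect_lt(max(abs(c(same$x, same$y, same$z))), 1e-9)

  roll <- relative_orientation(mk(x = 45), mk())
  expect_equal(unique(round(roll$x, 9)), 45)

  # common-mode rejection: both segments rotated identically about Y
  cm <- relative_orientation(mk(y = 25), mk(y = 25))
  expect_lt(max(abs(c(cm$x, cm$y, cm$z))), 1e-9)

  expect_error(relative_orientation(mk(), mk()[1:10, ]),
               class = "vw_validation_error")
})

test_that("swapping hand and forearm transposes the recovered rotation", {
  rot3 <- function(e) {
    r <- e * pi / 180
    Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3, 3)
    Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3, 3)
    Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  mk <- function(e) structure(data.frame(t = 0, x = e[1], y = e[2], z = e[3],
                                         gimbal = FALSE),
                              class = c("orientation_series", "data.frame"))
  set.seed(5)
  for (i in 1:50) {
    h <- runif(3, -60, 60); f <- runif(3, -60, 60)
    fwd <- relative_orientation(mk(h), mk(f))
    bwd <- relative_orientation(mk(f), mk(h))
    expect_equal(rot3(c(bwd$x, bwd$y, bwd$z)),
                 t(rot3(c(fwd$x, fwd$y, fwd$z))), tolerance = 1e-9)
  }
})

test_that("wrist angles of a static neutral session stay near zero", {
  ang <- wrist_angles(static_session())
  expect_lt(max(abs(c(ang$x, ang$y, ang$z))), 0.5)
})

test_that("wrist angles recover a held 60-degree flexion from synthetic streams", {
  tr <- generate_reference_trial(60, "X", noise = noise_free())
  hp <- hold_phase_angles(wrist_angles(tr$session), tr)
  expect_lt(max(abs(hp$x - 60)), 1)
  expect_lt(max(abs(c(hp$y, hp$z))), 1)
})
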