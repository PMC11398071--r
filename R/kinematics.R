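# Homogeneous-transform algebra, the three-sensor arm model, forward
# kinematics of the hand segment, and wrist-angle extraction as the relative
# orientation of hand vs forearm.

# 3x3 rotation blocks (angles in degrees)
rot3_x <- function(theta_deg) {
  r <- deg2rad(theta_deg); c <- cos(r); s <- sin(r)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot3_y <- function(theta_deg) {
  r <- deg2rad(theta_deg); c <- cos(r); s <- sin(r)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot3_z <- function(theta_deg) {
  r <- deg2rad(theta_deg); c <- cos(r); s <- sin(r)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# fixed-axis X-then-Y-then-Z composition, the convention used throughout
rot3_xyz <- function(euler_deg) {
  rot3_x(euler_deg[1]) %*% rot3_y(euler_deg[2]) %*% rot3_z(euler_deg[3])
}

as_homogeneous_transform <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || any(dim(m) != c(4L, 4L)))
    vw_validation_error("homogeneous transform must be a 4x4 matrix")
  if (any(m[4, ] != c(0, 0, 0, 1)))
    vw_validation_error("bottom row must be exactly (0, 0, 0, 1)")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol)
    vw_validation_error("rotation block is not orthonormal")
  if (abs(det(R) - 1) > tol)
    vw_validation_error("rotation block must have determinant +1")
  structure(m, class = c("homogeneous_transform", class(matrix())))
}

#' Homogeneous translation matrix
#'
#' @param dx,dy,dz Translation distances along x, y, z (metres).
#' @return A 4x4 matrix of class `homogeneous_transform` with identity
#'   rotation block.
#' @export
translation <- function(dx, dy, dz) {
  stopifnot_finite(c(dx, dy, dz), "translation distances")
  m <- diag(4)
  m[1:3, 4] <- c(dx, dy, dz)
  as_homogeneous_transform(m)
}

#' Homogeneous rotation matrices about the cardinal axes
#'
#' Right-handed rotations about x, y, z with angles in degrees.
#'
#' @param theta_deg Rotation angle in degrees.
#' @return A 4x4 `homogeneous_transform`.
#' @export
rotation_x <- function(theta_deg) {
  stopifnot_finite(theta_deg, "angle")
  m <- diag(4); m[1:3, 1:3] <- rot3_x(theta_deg)
  as_homogeneous_transform(m)
}

#' @rdname rotation_x
#' @export
rotation_y <- function(theta_deg) {
  stopifnot_finite(theta_deg, "angle")
  m <- diag(4); m[1:3, 1:3] <- rot3_y(theta_deg)
  as_homogeneous_transform(m)
}

#' @rdname rotation_x
#' @export
rotation_z <- function(theta_deg) {
  stopifnot_finite(theta_deg, "angle")
  m <- diag(4); m[1:3, 1:3] <- rot3_z(theta_deg)
  as_homogeneous_transform(m)
}

#' Combined rototranslation
#'
#' The product `translation(dx, dy, dz) %*% Rx(theta_x) %*% Ry(theta_y) %*%
#' Rz(theta_z)`, in exactly that order.
#'
#' @param dx,dy,dz Translation distances (metres).
#' @param theta_x,theta_y,theta_z Rotation angles (degrees).
#' @return A 4x4 `homogeneous_transform`.
#' @export
rototranslate <- function(dx = 0, dy = 0, dz = 0,
                          theta_x = 0, theta_y = 0, theta_z = 0) {
  m <- translation(dx, dy, dz) %*% rotation_x(theta_x) %*%
    rotation_y(theta_y) %*% rotation_z(theta_z)
  as_homogeneous_transform(m)
}

#' Apply a homogeneous transform to 3-D points
#'
#' @param transform A 4x4 `homogeneous_transform`.
#' @param points Length-3 vector or n-by-3 matrix.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else as.matrix(points)
  out <- t(transform %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  if (single) as.numeric(out) else out
}

#' Three-sensor arm model
#'
#' Geometry of the instrumented hand-wrist-forearm system: sensor S1 sits on
#' the wrist rotation axis (point A), S2 at the midpoint of the hand segment
#' AB (A to the middle-finger point B/N), S3 at the midpoint of the forearm
#' segment AC (A to the elbow rotation axis C/M). All sensors are aligned
#' along the Y axis, so the resting hand segment points along +Y of the
#' forearm frame.
#'
#' @param len_ab Hand-segment length A-B in metres (default 0.18).
#' @param len_ac Forearm-segment length A-C in metres (default 0.26).
#' @return A list of class `arm_model` with segment lengths and the S2/S3
#'   offsets from A (half of each segment).
#' @export
arm_model <- function(len_ab = 0.18, len_ac = 0.26) {
  if (!is.numeric(len_ab) || !is.numeric(len_ac) || len_ab <= 0 || len_ac <= 0)
    vw_validation_error("segment lengths must be > 0")
  structure(list(len_ab = len_ab, len_ac = len_ac,
                 s2_offset = len_ab / 2, s3_offset = len_ac / 2),
            class = "arm_model")
}

#' Forward kinematics of the hand segment
#'
#' Poses the hand segment (length `len_ab`, resting along +Y) in the forearm
#' frame for a given wrist Euler triplet, via
#' `rototranslate(0, 0, 0, theta_x, theta_y, theta_z)`.
#'
#' @param model An [arm_model()].
#' @param euler_deg Wrist angles `c(x, y, z)` in degrees.
#' @return List with `N` (end-effector/middle-finger point), `S2` (hand
#'   sensor at half length) and `transform` (the 4x4 pose).
#' @export
forward_kinematics <- function(model, euler_deg) {
  stopifnot_finite(euler_deg, "euler_deg")
  tr <- rototranslate(0, 0, 0, euler_deg[1], euler_deg[2], euler_deg[3])
  list(N = apply_transform(tr, c(0, model$len_ab, 0)),
       S2 = apply_transform(tr, c(0, model$s2_offset, 0)),
       transform = tr)
}

# Euler extraction for R = Rx(a) Ry(b) Rz(c); returns degrees + gimbal flag.
# Near |pitch| = 90 the roll/yaw pair is degenerate: the coupled sum is
# assigned to roll and yaw is set to 0, with the flag raised.
euler_from_rot3 <- function(R, gimbal_tol = sin(deg2rad(89))) {
  s_y <- max(-1, min(1, R[1, 3]))
  if (abs(s_y) > gimbal_tol) {
    list(euler = c(rad2deg(atan2(R[3, 2], R[2, 2])), rad2deg(asin(s_y)), 0),
         gimbal = TRUE)
  } else {
    list(euler = c(rad2deg(atan2(-R[2, 3], R[3, 3])), rad2deg(asin(s_y)),
                   rad2deg(atan2(-R[1, 2], R[1, 1]))),
         gimbal = FALSE)
  }
}

#' Relative orientation of the hand with respect to the forearm
#'
#' Per synchronized frame, decomposes `R_forearm' R_hand` into fixed-axis
#' X-then-Y-then-Z Euler angles: the wrist joint angles.
#'
#' @param hand,forearm `orientation_series` objects on the identical time
#'   grid.
#' @return A data frame of class `joint_angle_series` with columns
#'   `t, x, y, z, gimbal` (degrees).
#' @export
relative_orientation <- function(hand, forearm) {
  if (nrow(hand) != nrow(forearm) || max(abs(hand$t - forearm$t)) > 1e-9)
    vw_validation_error("hand and forearm series are on different time grids")
  eh <- euler_matrix(hand); ef <- euler_matrix(forearm)
  n <- nrow(eh)
  out <- matrix(0, n, 3)
  gim <- logical(n)
  for (i in seq_len(n)) {
    Rrel <- t(rot3_xyz(ef[i, ])) %*% rot3_xyz(eh[i, ])
    e <- euler_from_rot3(Rrel)
    out[i, ] <- e$euler
    gim[i] <- e$gimbal
  }
  structure(data.frame(t = hand$t, x = out[, 1], y = out[, 2], z = out[, 3],
                       gimbal = gim),
            class = c("joint_angle_series", "data.frame"))
}

#' Wrist joint angles for a whole session
#'
#' The full estimation pipeline: synchronize the three streams (if not
#' already synchronized), fuse the hand-segment sensor S2 and the
#' forearm-segment sensor S3 into orientation series, and take their relative
#' orientation. S1 (on the joint axis) is reserved for event reference and cut
#' detection.
#'
#' @param session An [imu_session()] or a `synced_session` from
#'   [round_robin_sync()].
#' @param config A [filter_config()].
#' @param rate,max_skew Synchronization parameters, see [round_robin_sync()].
#' @return A `joint_angle_series` (degrees, hand relative to forearm).
#' @export
wrist_angles <- function(session, config = filter_config(),
                         rate = NULL, max_skew = NULL) {
  synced <- if (inherits(session, "synced_session")) session
            else round_robin_sync(session, rate = rate, max_skew = max_skew)
  hand <- fuse_orientation(synced$streams$S2, config)
  forearm <- fuse_orientation(synced$streams$S3, config)
  relative_orientation(hand, forearm)
}
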