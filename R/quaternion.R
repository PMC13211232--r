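# Quaternion helpers. Convention: q = (w, x, y, z), unit norm, Hamilton
# product. Euler angles use the intrinsic X-Y-Z (roll-pitch-yaw) convention,
# i.e. R = Rx(roll) %*% Ry(pitch) %*% Rz(yaw); the same convention is used for
# posture presets, preset perturbation and fully-random orientation sampling.

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
  q / n
}

quat_mul <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis * axis))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' @noRd
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_rotate <- function(q, v) as.vector(quat_to_matrix(q) %*% v)

# intrinsic X-Y-Z: R = Rx(roll) Ry(pitch) Rz(yaw)
quat_from_euler <- function(roll, pitch, yaw) {
  qx <- quat_axis_angle(c(1, 0, 0), roll)
  qy <- quat_axis_angle(c(0, 1, 0), pitch)
  qz <- quat_axis_angle(c(0, 0, 1), yaw)
  quat_mul(quat_mul(qx, qy), qz)
}

# inverse of quat_from_euler (pitch in [-pi/2, pi/2])
quat_to_euler <- function(q) {
  R <- quat_to_matrix(q)
  pitch <- asin(max(-1, min(1, R[1, 3])))
  if (abs(R[1, 3]) < 1 - 1e-9) {
    roll <- atan2(-R[2, 3], R[3, 3])
    yaw <- atan2(-R[1, 2], R[1, 1])
  } else { # gimbal lock: yaw set to 0
    roll <- atan2(R[3, 2], R[2, 2])
    yaw <- 0
  }
  c(roll = roll, pitch = pitch, yaw = yaw)
}

# uniform on SO(3) via normalised 4D Gaussian (uniform on the 3-sphere)
quat_random_uniform <- function() quat_normalize(rnorm(4))

quat_slerp <- function(a, b, t) {
  d <- sum(a * b)
  if (d < 0) { b <- -b; d <- -d }
  if (d > 1 - 1e-10) return(quat_normalize(a + t * (b - a)))
  th <- acos(min(1, d))
  quat_normalize((sin((1 - t) * th) * a + sin(t * th) * b) / sin(th))
}
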