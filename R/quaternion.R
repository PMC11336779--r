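## Quaternion utilities (scalar-first convention, q = (w, x, y, z)).
## A quaternion here always encodes the rotation from the DEVICE frame to the
## gravity-aligned GLOBAL frame: v_global = R(q) %*% v_device.
## All helpers are internal; user-facing code works with OrientationSeries.

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < .Machine$double.eps) stop_compute("cannot normalize zero quaternion")
  q / n
}

quat_mul <- function(p, q) {
  c(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]
  )
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

## 3x3 rotation matrix R(q): v_global = R %*% v_device
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_rotate <- function(q, v) as.numeric(quat_to_matrix(q) %*% v)

quat_rotate_inv <- function(q, v) as.numeric(crossprod(quat_to_matrix(q), v))

quat_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

## Minimal rotation taking unit vector a onto unit vector b
## (half-angle construction; antipodal case resolved about a perpendicular).
quat_between <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d < -1 + 1e-12) {
    perp <- vec3_cross(a, c(1, 0, 0))
    if (sum(perp^2) < 1e-12) perp <- vec3_cross(a, c(0, 1, 0))
    return(quat_axis_angle(perp, pi))
  }
  quat_normalize(c(1 + d, vec3_cross(a, b)))
}

vec3_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
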