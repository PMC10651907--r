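# Unit-quaternion algebra on (w, x, y, z) rows. All functions accept either a
# length-4 vector or an n x 4 matrix and are vectorized over rows. Rotations
# are right-handed; q and -q encode the same rotation, canonical sign w >= 0.

#' Construct a unit quaternion from axis and angle
#'
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees, right-handed about `axis`.
#' @return length-4 numeric `(w, x, y, z)`, canonicalized to `w >= 0`.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  check_finite(c(axis, angle_deg), "axis/angle")
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop_invalid("rotation axis has zero length")
  h <- angle_deg * pi / 360
  quat_canonical(c(cos(h), sin(h) * axis / n))
}

#' @keywords internal
quat_norm <- function(q) {
  q <- as_row_matrix(q, 4L)
  sqrt(rowSums(q^2))
}

#' Normalize quaternion rows to unit norm
#' @param q length-4 vector or n x 4 matrix.
#' @export
quat_normalize <- function(q) {
  was_vec <- !is.matrix(q)
  q <- as_row_matrix(q, 4L)
  n <- quat_norm(q)
  if (any(n < 1e-12)) stop_invalid("cannot normalize a zero quaternion")
  out <- q / n
  if (was_vec) out[1, ] else out
}

#' Canonicalize quaternion sign so that w >= 0
#' @param q length-4 vector or n x 4 matrix.
#' @export
quat_canonical <- function(q) {
  was_vec <- !is.matrix(q)
  q <- as_row_matrix(q, 4L)
  s <- ifelse(q[, 1] < 0, -1, 1)
  out <- q * s
  if (was_vec) out[1, ] else out
}

#' @keywords internal
check_unit_quat <- function(q, tol = 1e-6, what = "quaternion") {
  n <- quat_norm(q)
  if (any(abs(n - 1) > tol)) stop_invalid(what, " is not unit-norm")
  invisible(q)
}

#' Hamilton product of quaternions (rowwise)
#' @param a,b length-4 vectors or n x 4 matrices (recycled rowwise).
#' @export
quat_multiply <- function(a, b) {
  was_vec <- !is.matrix(a) && !is.matrix(b)
  a <- as_row_matrix(a, 4L); b <- as_row_matrix(b, 4L)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  out <- cbind(w, x, y, z, deparse.level = 0)
  if (was_vec) out[1, ] else out
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(q) {
  was_vec <- !is.matrix(q)
  q <- as_row_matrix(q, 4L)
  out <- cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4], deparse.level = 0)
  if (was_vec) out[1, ] else out
}

#' Rotate 3-vectors by unit quaternions (rowwise)
#'
#' @param q length-4 vector or n x 4 matrix of unit quaternions.
#' @param v length-3 vector or n x 3 matrix of vectors.
#' @return rotated vectors, same shape convention as `v`.
#' @export
quat_rotate <- function(q, v) {
  was_vec <- !is.matrix(v)
  q <- as_row_matrix(q, 4L); v <- as_row_matrix(v, 3L)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v), u = (x,y,z)
  u <- q[, 2:4, drop = FALSE]
  w <- q[, 1]
  uv <- cross3(u, v)
  uuv <- cross3(u, uv)
  out <- v + 2 * w * uv + 2 * uuv
  if (was_vec) out[1, ] else out
}

#' @keywords internal
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1], deparse.level = 0)
}

#' Spherical linear interpolation between two unit quaternions
#'
#' Interpolates along the shorter arc; `u` may be a vector, giving one row per
#' fraction.
#'
#' @param q0,q1 unit quaternions (length-4).
#' @param u interpolation fraction(s) in `[0, 1]`.
#' @return n x 4 matrix (or length-4 vector when `u` is scalar).
#' @export
quat_slerp <- function(q0, q1, u) {
  check_finite(c(q0, q1, u), "slerp inputs")
  check_unit_quat(q0); check_unit_quat(q1)
  if (any(u < -1e-12 | u > 1 + 1e-12)) stop_invalid("slerp fraction outside [0, 1]")
  u <- pmin(pmax(u, 0), 1)
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  d <- min(d, 1)
  if (d > 1 - 1e-12) {
    out <- outer(1 - u, q0) + outer(u, q1)
    out <- out / sqrt(rowSums(out^2))
  } else {
    th <- acos(d)
    out <- (outer(sin((1 - u) * th), q0) + outer(sin(u * th), q1)) / sin(th)
  }
  out <- quat_canonical(out)
  if (length(u) == 1L) out[1, ] else out
}

#' Convert a unit quaternion to a 3 x 3 rotation matrix
#' @param q length-4 unit quaternion.
#' @export
quat_to_matrix <- function(q) {
  check_unit_quat(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a canonical unit quaternion
#' @param R 3 x 3 proper rotation matrix.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_canonical(quat_normalize(q))
}

#' Orientation whose forward (+x) axis points along `forward`
#'
#' Head convention: +x forward, +y left, +z up (right-handed). The up axis is
#' kept as close to world +z as possible.
#'
#' @param forward length-3 direction (need not be unit).
#' @return length-4 unit quaternion.
#' @export
quat_look_at <- function(forward) {
  f <- forward / sqrt(sum(forward^2))
  up <- c(0, 0, 1)
  if (abs(sum(f * up)) > 1 - 1e-9) up <- c(0, 1, 0)
  l <- cross3(matrix(up, 1), matrix(f, 1))[1, ] # left = up x forward
  l <- l / sqrt(sum(l^2))
  u <- cross3(matrix(f, 1), matrix(l, 1))[1, ]
  matrix_to_quat(cbind(f, l, u))
}
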