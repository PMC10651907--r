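# World frame: right-handed, x-y = floor plane, z = up, meters; origin at the
# arena corner nearest the curtain. Poses are lists with fields t (seconds,
# trial-relative), p (length-3 position, m) and q (length-4 unit quaternion).

#' Create a 6-DOF pose
#'
#' @param t timestamp in seconds (trial-relative, `t >= 0`).
#' @param p length-3 position in meters.
#' @param q length-4 unit quaternion `(w, x, y, z)`.
#' @return a `pose6dof` list.
#' @export
pose6dof <- function(t, p, q = c(1, 0, 0, 0)) {
  check_finite(c(t, p, q), "pose")
  if (t < 0) stop_invalid("pose timestamp must be >= 0")
  check_unit_quat(q, what = "pose orientation")
  structure(list(t = t, p = as.numeric(p), q = quat_canonical(as.numeric(q))),
            class = "pose6dof")
}

#' @keywords internal
unit3 <- function(v) {
  was_vec <- !is.matrix(v)
  v <- as_row_matrix(v, 3L)
  n <- sqrt(rowSums(v^2))
  if (any(n < 1e-12)) stop_invalid("cannot normalize a zero direction")
  out <- v / n
  if (was_vec) out[1, ] else out
}

#' Angle in degrees between paired unit direction rows
#' @param a,b length-3 vectors or n x 3 matrices of unit directions.
#' @export
angle_between_deg <- function(a, b) {
  a <- as_row_matrix(a, 3L); b <- as_row_matrix(b, 3L)
  d <- pmin(pmax(rowSums(a * b), -1), 1)
  acos(d) * 180 / pi
}

#' Interpolate between two poses
#'
#' Position is interpolated linearly, orientation geodesically along the
#' shorter arc (slerp). Used to place the 120 Hz head stream at 50 Hz gaze
#' timestamps.
#'
#' @param p0,p1 `pose6dof` with `p0$t < p1$t`.
#' @param u fraction in `[0, 1]`; `u = 0` returns `p0`, `u = 1` returns `p1`.
#' @return interpolated `pose6dof`.
#' @export
slerp_pose <- function(p0, p1, u) {
  check_finite(c(p0$t, p0$p, p0$q, p1$t, p1$p, p1$q, u), "slerp_pose inputs")
  if (p0$t >= p1$t) stop_invalid("slerp_pose requires p0$t < p1$t")
  if (u < 0 || u > 1) stop_invalid("interpolation fraction must lie in [0, 1]")
  pose6dof(t = (1 - u) * p0$t + u * p1$t,
           p = (1 - u) * p0$p + u * p1$p,
           q = quat_slerp(p0$q, p1$q, u))
}

#' Geodesic angle between two rotations, in degrees
#'
#' The rotation angle of `q1' * q2`, in `[0, 180]`; symmetric in its
#' arguments. This is the orientation-difference measure used for the
#' stimulus factor levels 0/90/180 degrees.
#'
#' @param q1,q2 length-4 unit quaternions.
#' @export
angular_difference <- function(q1, q2) {
  check_finite(c(q1, q2), "quaternions")
  check_unit_quat(q1); check_unit_quat(q2)
  d <- abs(sum(q1 * q2))
  2 * acos(min(d, 1)) * 180 / pi
}

#' Per-sample angular speed of a direction series, deg/s
#'
#' Central differences for interior samples and one-sided differences at the
#' two ends; the angle between directions is the arccos of the clamped dot
#' product. At the nominal 50 Hz gaze rate the central difference spans 40 ms,
#' the smallest-lag symmetric estimate.
#'
#' @param dirs n x 3 matrix of unit directions.
#' @param ts strictly increasing timestamps, seconds.
#' @return numeric vector of length n, degrees per second.
#' @export
angular_velocity_series <- function(dirs, ts) {
  dirs <- as_row_matrix(dirs, 3L)
  n <- nrow(dirs)
  if (n < 2L || length(ts) != n) stop_invalid("need >= 2 samples with matching timestamps")
  check_finite(dirs, "directions"); check_finite(ts, "timestamps")
  if (any(diff(ts) <= 0)) stop_invalid("timestamps must be strictly increasing")
  v <- numeric(n)
  if (n > 2L) {
    i <- 2:(n - 1)
    v[i] <- angle_between_deg(dirs[i - 1, , drop = FALSE], dirs[i + 1, , drop = FALSE]) /
      (ts[i + 1] - ts[i - 1])
  }
  v[1] <- angle_between_deg(dirs[1, ], dirs[2, ]) / (ts[2] - ts[1])
  v[n] <- angle_between_deg(dirs[n - 1, ], dirs[n, ]) / (ts[n] - ts[n - 1])
  v
}

#' Head-path length with a noise floor
#'
#' Anchored integration: displacement accumulates from the last anchor point
#' and is added to the total (moving the anchor) only once it reaches
#' `min_step`. With `min_step = 0` this is the naive polyline sum. The default
#' floor used downstream is 2 mm, an order of magnitude above the 0.2 mm RMSE
#' position noise of a marker-based tracker, so stationary jitter does not
#' accumulate into spurious meters.
#'
#' @param positions n x 3 matrix of positions, meters.
#' @param min_step anchor threshold in meters, `>= 0`.
#' @return total path length in meters.
#' @export
path_length <- function(positions, min_step = 0) {
  positions <- as_row_matrix(positions, 3L)
  if (nrow(positions) < 1L) stop_invalid("path_length needs at least one position")
  check_finite(positions, "positions")
  if (min_step < 0) stop_invalid("min_step must be >= 0")
  n <- nrow(positions)
  if (n == 1L) return(0)
  if (min_step == 0) {
    return(sum(sqrt(rowSums(diff(positions)^2))))
  }
  total <- 0
  anchor <- positions[1, ]
  for (i in 2:n) {
    d <- positions[i, ] - anchor
    dist <- sqrt(sum(d * d))
    if (dist >= min_step) {
      total <- total + dist
      anchor <- positions[i, ]
    }
  }
  total
}
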