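# Shared fixtures, built in code.

# Rodrigues rotation matrix, independent of the package's quaternion route.
rot_matrix_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# All 24 proper signed-permutation matrices, enumerated in the test's own code.
proper_lattice_rotations <- function() {
  out <- list()
  for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
      R <- matrix(0, 3, 3)
      R[1, p[1]] <- s1; R[2, p[2]] <- s2; R[3, p[3]] <- s3
      if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1L]] <- R
    }
  }
  out
}

# Synced-stream builder: stationary head at the origin with identity
# orientation, world gaze directions given per row.
make_synced <- function(dirs, ts) {
  n <- nrow(dirs)
  data.frame(t_s = ts, px_m = 0, py_m = 0, pz_m = 0,
             qw = 1, qx = 0, qy = 0, qz = 0,
             dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
}

# Direction rotating about z at a constant rate (deg/s), starting at +x.
rotating_dirs <- function(ts, rate_deg_s, start_deg = 0) {
  a <- (start_deg + rate_deg_s * ts) * pi / 180
  cbind(cos(a), sin(a), 0)
}

# Unit directions in the x-y plane at the given angles (degrees) from +x.
dirs_at_angles <- function(deg) {
  a <- deg * pi / 180
  cbind(cos(a), sin(a), 0)
}

# Brute-force run-length grouping oracle (independent of the package code).
grouping_oracle <- function(labels) {
  obj <- labels[labels != "environment"]
  counts <- setNames(integer(9), c(as.character(1:8), "higher"))
  if (!length(obj)) return(counts)
  lens <- integer(0)
  cur <- 1L
  if (length(obj) > 1) {
    for (i in 2:length(obj)) {
      if (obj[i] == obj[i - 1]) cur <- cur + 1L
      else { lens <- c(lens, cur); cur <- 1L }
    }
  }
  lens <- c(lens, cur)
  for (l in lens) {
    b <- if (l > 8) "higher" else as.character(l)
    counts[b] <- counts[b] + 1L
  }
  counts
}

# A chiral pentacube and its mirror image across the x-plane.
chiral_pentacube <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0), c(2, 1, 1))
}
mirror_x <- function(cells) {
  m <- cells
  m[, 1] <- -m[, 1]
  m
}

empty_fixations_df <- function() activegaze:::empty_fixations()

# One default-parameter simulated trial record.
demo_record <- function(complexity = "C_m", start = "P_l", orient = 90, same = TRUE) {
  list(subject_id = "S01", trial_index = 1L, complexity = complexity,
       start_position = start, orientation_diff_deg = orient, same = same)
}
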