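make_head <- function(ts, q = c(1, 0, 0, 0), p = c(0, 0, 0)) {
  data.frame(t_s = ts, px_m = p[1], py_m = p[2], pz_m = p[3],
             qw = q[1], qx = q[2], qy = q[3], qz = q[4])
}

test_that("stream CSVs round-trip to 1e-9 and validate their schemas", {
  hd <- withr::local_tempfile(fileext = ".csv")
  gz <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  q <- quat_normalize(rnorm(4))
  head <- data.frame(t_s = c(0, 1 / 120), px_m = runif(2), py_m = runif(2),
                     pz_m = runif(2), qw = q[1], qx = q[2], qy = q[3], qz = q[4])
  d <- c(0.3, 0.4, sqrt(1 - 0.25))
  gaze <- data.frame(t_s = c(0, 0.02), gx = d[1], gy = d[2], gz = d[3], valid = c(1, 1))
  write_head_csv(head, hd); write_gaze_csv(gaze, gz)
  st <- read_streams(hd, gz)
  expect_equal(nrow(st$head), 2)
  expect_equal(nrow(st$gaze), 2)
  expect_equal(as.matrix(st$head), as.matrix(head), tolerance = 1e-9)
  expect_equal(as.matrix(st$gaze), as.matrix(gaze), tolerance = 1e-9)

  bad <- head; bad$t_s <- c(0.5, 0.5)
  write_head_csv(bad, hd)
  expect_error(read_head_csv(hd), "non-monotonic.*row 2")
  writeLines(c("t_s,px_m", "0,0"), hd)
  expect_error(read_head_csv(hd), "missing column")
})

test_that("invalid gaze rows are flagged, not dropped", {
  gz <- withr::local_tempfile(fileext = ".csv")
  gaze <- data.frame(t_s = c(0, 0.02, 0.04), gx = c(1, 5, 1), gy = 0, gz = 0,
                     valid = c(1, 1, 0))
  write_gaze_csv(gaze, gz)
  g <- read_gaze_csv(gz)
  expect_equal(nrow(g), 3)
  expect_equal(g$valid, c(1L, 0L, 0L)) # non-unit direction demoted to invalid
})

test_that("synchronize interpolates the head pose at gaze timestamps", {
  q10 <- quat_from_axis_angle(c(0, 0, 1), 10)
  head <- rbind(make_head(0), make_head(0.02, q = q10, p = c(1, 0, 0)))
  gaze <- data.frame(t_s = c(0, 0.01, 0.02), gx = 1, gy = 0, gz = 0, valid = 1)
  sy <- synchronize(head, gaze)
  expect_equal(nrow(sy), 3)
  # coincident timestamps give the exact head pose
  expect_equal(unlist(sy[1, c("qw", "qx", "qy", "qz")], use.names = FALSE), c(1, 0, 0, 0))
  # midway between samples 10 deg apart: 5 deg interpolated orientation
  expect_equal(angular_difference(c(1, 0, 0, 0),
                                  unlist(sy[2, c("qw", "qx", "qy", "qz")], use.names = FALSE)),
               5, tolerance = 1e-9)
  expect_equal(unlist(sy[2, c("px_m", "py_m", "pz_m")], use.names = FALSE), c(0.5, 0, 0))
  # identity frame: world ray equals the head-frame direction at the origin
  expect_equal(unlist(sy[1, c("dx", "dy", "dz")], use.names = FALSE), c(1, 0, 0))
})

test_that("synchronize drops out-of-span and gap samples with logged counts", {
  head <- rbind(make_head(0), make_head(0.01), make_head(0.2)) # 190 ms gap
  gaze <- data.frame(t_s = c(-0.01, 0.005, 0.1, 0.25), gx = 1, gy = 0, gz = 0,
                     valid = c(1, 1, 1, 1))
  sy <- synchronize(head, gaze)
  expect_equal(nrow(sy), 1) # only t = 0.005 survives
  dropped <- attr(sy, "dropped")
  expect_equal(unname(dropped["out_of_span"]), 2)
  expect_equal(unname(dropped["head_gap"]), 1)
  expect_error(synchronize(head, data.frame(t_s = 9, gx = 1, gy = 0, gz = 0, valid = 1)),
               "no valid gaze")
})

test_that("synchronization commutes with a rigid world-frame change", {
  set.seed(3)
  ts_h <- seq(0, 0.2, by = 1 / 120)
  qs <- t(sapply(ts_h, function(t) quat_from_axis_angle(c(0, 0, 1), 40 * t)))
  head <- data.frame(t_s = ts_h, px_m = ts_h, py_m = 0.2 * ts_h, pz_m = 1.6,
                     qw = qs[, 1], qx = qs[, 2], qy = qs[, 3], qz = qs[, 4])
  gaze <- data.frame(t_s = seq(0.01, 0.19, by = 0.02),
                     gx = 0.8, gy = 0.6, gz = 0, valid = 1)
  sy1 <- synchronize(head, gaze)

  qT <- quat_from_axis_angle(c(0.2, -0.3, 1), 63)
  tT <- c(0.4, -1.2, 0.3)
  P2 <- t(apply(as.matrix(head[, c("px_m", "py_m", "pz_m")]), 1,
                function(p) quat_rotate(qT, p) + tT))
  Q2 <- t(apply(as.matrix(head[, c("qw", "qx", "qy", "qz")]), 1,
                function(q) quat_multiply(qT, q)))
  head2 <- data.frame(t_s = ts_h, px_m = P2[, 1], py_m = P2[, 2], pz_m = P2[, 3],
                      qw = Q2[, 1], qx = Q2[, 2], qy = Q2[, 3], qz = Q2[, 4])
  sy2 <- synchronize(head2, gaze)
  D1t <- t(apply(as.matrix(sy1[, c("dx", "dy", "dz")]), 1, function(d) quat_rotate(qT, d)))
  O1t <- t(apply(as.matrix(sy1[, c("px_m", "py_m", "pz_m")]), 1,
                 function(p) quat_rotate(qT, p) + tT))
  expect_equal(as.matrix(sy2[, c("dx", "dy", "dz")]), D1t,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(as.matrix(sy2[, c("px_m", "py_m", "pz_m")]), O1t,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("trial JSON round-trips and validates required fields", {
  f <- withr::local_tempfile(fileext = ".json")
  tr <- list(subject_id = "S01", trial_index = 3L, complexity = "C_m",
             start_position = "P_c", orientation_diff_deg = 90, same = TRUE,
             answer = "same", answer_time_s = 41.25)
  write_trial_json(tr, f)
  tr2 <- read_trial_json(f)
  expect_equal(tr2[names(tr)], tr)
  write_trial_json(tr[-1], f)
  expect_error(read_trial_json(f), "missing field")
})

test_that("object-pose CSV round-trips per-object tracks", {
  f <- withr::local_tempfile(fileext = ".csv")
  mk <- function(x) data.frame(t_s = c(0, 1 / 120), px_m = x, py_m = 2.6, pz_m = 1.2,
                               qw = 1, qx = 0, qy = 0, qz = 0)
  write_object_pose_csv(list(object1 = mk(1.5), object2 = mk(1.9)), f)
  got <- read_object_pose_csv(f)
  expect_named(got, c("object1", "object2"))
  expect_equal(got$object2$px_m, c(1.9, 1.9), tolerance = 1e-9)
  writeLines(c("t_s,px_m", "0,1"), f)
  expect_error(read_object_pose_csv(f), "object_id")
})
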