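# Stream file formats and head/gaze synchronization.
#
# head CSV:   t_s, px_m, py_m, pz_m, qw, qx, qy, qz
# gaze CSV:   t_s, gx, gy, gz, valid          (gaze direction in the head frame)
# object CSV: object_id + head schema
# trial JSON: subject_id, trial_index, complexity, start_position,
#             orientation_diff_deg, same, answer, answer_time_s
#
# Timestamps are float seconds with microsecond resolution, trial-relative
# (t = 0 at the first head sample). Gaze is stored as a head-frame direction:
# the minimal device-independent representation.

HEAD_COLS <- c("t_s", "px_m", "py_m", "pz_m", "qw", "qx", "qy", "qz")
GAZE_COLS <- c("t_s", "gx", "gy", "gz", "valid")

#' @keywords internal
check_stream_df <- function(df, cols, what, path = "<data>") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop_format(what, " stream ", path, " is missing column(s): ",
                                paste(miss, collapse = ", "))
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad)) stop_format(what, " stream ", path,
                               ": non-monotonic timestamp at row ", bad[1] + 1L)
  invisible(df)
}

#' Read a head-pose or gaze stream
#'
#' Rows of a gaze stream whose direction is not finite or not unit-norm are
#' flagged `valid = 0`, not dropped. Non-monotonic timestamps or missing
#' columns raise a format error naming the row/column.
#'
#' @param head_path,gaze_path CSV paths conforming to the schemas above.
#' @return `read_streams` returns `list(head = <data.frame>, gaze = <data.frame>)`.
#' @export
read_streams <- function(head_path, gaze_path) {
  list(head = read_head_csv(head_path), gaze = read_gaze_csv(gaze_path))
}

#' @rdname read_streams
#' @export
read_head_csv <- function(head_path) {
  df <- utils::read.csv(head_path)
  check_stream_df(df, HEAD_COLS, "head", head_path)
  qn <- sqrt(df$qw^2 + df$qx^2 + df$qy^2 + df$qz^2)
  if (any(abs(qn - 1) > 1e-6)) {
    stop_format("head stream ", head_path, ": non-unit quaternion at row ",
                which(abs(qn - 1) > 1e-6)[1])
  }
  df[HEAD_COLS]
}

#' @rdname read_streams
#' @export
read_gaze_csv <- function(gaze_path) {
  df <- utils::read.csv(gaze_path)
  check_stream_df(df, GAZE_COLS, "gaze", gaze_path)
  gn <- sqrt(df$gx^2 + df$gy^2 + df$gz^2)
  ok <- is.finite(gn) & abs(gn - 1) < 1e-6
  df$valid <- as.integer(df$valid != 0 & ok)
  df[GAZE_COLS]
}

#' Write streams with fixed decimal formatting
#'
#' Fixed decimal formats (1e-9 on every field) make re-runs byte-identical and
#' round-trips exact to 1e-9.
#'
#' @param head,gaze stream data frames.
#' @param path output CSV path.
#' @export
write_head_csv <- function(head, path) {
  out <- data.frame(t_s = sprintf("%.9f", head$t_s),
                    px_m = sprintf("%.9f", head$px_m),
                    py_m = sprintf("%.9f", head$py_m),
                    pz_m = sprintf("%.9f", head$pz_m),
                    qw = sprintf("%.9f", head$qw), qx = sprintf("%.9f", head$qx),
                    qy = sprintf("%.9f", head$qy), qz = sprintf("%.9f", head$qz))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_head_csv
#' @export
write_gaze_csv <- function(gaze, path) {
  out <- data.frame(t_s = sprintf("%.9f", gaze$t_s),
                    gx = sprintf("%.9f", gaze$gx), gy = sprintf("%.9f", gaze$gy),
                    gz = sprintf("%.9f", gaze$gz), valid = as.integer(gaze$valid))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write an object-pose stream (head schema plus an object_id column)
#'
#' Stimulus objects are static in this task, but the format carries full
#' per-timestamp pose tracks per object, mirroring a motion-capture export.
#'
#' @param path CSV path.
#' @return named list of per-object data frames in the head-stream schema.
#' @export
read_object_pose_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"object_id" %in% names(df)) stop_format("object-pose CSV ", path,
                                               " is missing column(s): object_id")
  out <- lapply(split(df, df$object_id), function(d) {
    rownames(d) <- NULL
    check_stream_df(d, HEAD_COLS, "object pose", path)
    d[HEAD_COLS]
  })
  out
}

#' @rdname read_object_pose_csv
#' @param poses named list of per-object data frames (head schema).
#' @export
write_object_pose_csv <- function(poses, path) {
  rows <- lapply(names(poses), function(id) cbind(object_id = id, poses[[id]]))
  df <- do.call(rbind, rows)
  out <- data.frame(object_id = df$object_id, t_s = sprintf("%.9f", df$t_s),
                    px_m = sprintf("%.9f", df$px_m), py_m = sprintf("%.9f", df$py_m),
                    pz_m = sprintf("%.9f", df$pz_m),
                    qw = sprintf("%.9f", df$qw), qx = sprintf("%.9f", df$qx),
                    qy = sprintf("%.9f", df$qy), qz = sprintf("%.9f", df$qz))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write trial metadata JSON
#' @param path JSON path.
#' @export
read_trial_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("subject_id", "trial_index", "complexity", "start_position",
           "orientation_diff_deg", "same", "answer", "answer_time_s")
  miss <- setdiff(req, names(tr))
  if (length(miss)) stop_format("trial JSON ", path, " missing field(s): ",
                                paste(miss, collapse = ", "))
  tr
}

#' @rdname read_trial_json
#' @param trial named list of trial fields.
#' @export
write_trial_json <- function(trial, path) {
  jsonlite::write_json(trial, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @keywords internal
# Row-wise slerp: q0, q1 are n x 4, u length n. Shorter arc.
slerp_rows <- function(q0, q1, u) {
  d <- rowSums(q0 * q1)
  flip <- d < 0
  q1[flip, ] <- -q1[flip, , drop = FALSE]
  d <- pmin(abs(d), 1)
  th <- acos(d)
  near <- th < 1e-6
  w0 <- ifelse(near, 1 - u, sin((1 - u) * th) / ifelse(near, 1, sin(th)))
  w1 <- ifelse(near, u, sin(u * th) / ifelse(near, 1, sin(th)))
  out <- q0 * w0 + q1 * w1
  out / sqrt(rowSums(out^2))
}

#' Synchronize the head stream to gaze timestamps
#'
#' For every valid gaze sample inside the head stream's time span, the head
#' pose is slerp-interpolated to the gaze timestamp (gaze is the lower-rate,
#' event-defining stream) and the head-frame gaze direction is rotated into
#' the world frame. The world gaze ray originates at the interpolated head
#' position. Gaze samples outside the head span, invalid samples, and samples
#' falling in head gaps longer than `max_head_gap` (default three nominal
#' 120 Hz periods) are dropped; counts are attached as the `"dropped"`
#' attribute.
#'
#' @param head head stream data frame (see [read_streams()]).
#' @param gaze gaze stream data frame.
#' @param max_head_gap seconds; head gaps longer than this are not
#'   interpolated across.
#' @return data frame with columns `t_s`, `px_m..pz_m`, `qw..qz` (interpolated
#'   head pose), `dx, dy, dz` (world gaze direction).
#' @export
synchronize <- function(head, gaze, max_head_gap = 0.025) {
  check_stream_df(head, HEAD_COLS, "head")
  check_stream_df(gaze, GAZE_COLS, "gaze")
  t_h <- head$t_s
  keep <- gaze$valid != 0 & gaze$t_s >= t_h[1] & gaze$t_s <= t_h[length(t_h)]
  n_out_span <- sum(gaze$valid != 0) - sum(keep)
  g <- gaze[keep, , drop = FALSE]
  if (nrow(g) == 0L) {
    stop(errorCondition("no valid gaze samples within the head stream span",
                        class = c("activegaze_sync_error", "error")))
  }
  i0 <- findInterval(g$t_s, t_h, rightmost.closed = TRUE)
  i1 <- pmin(i0 + 1L, length(t_h))
  exact <- g$t_s == t_h[i0]
  i1[exact] <- i0[exact]
  gap <- t_h[i1] - t_h[i0]
  in_gap <- !exact & gap > max_head_gap
  n_gap <- sum(in_gap)
  g <- g[!in_gap, , drop = FALSE]
  i0 <- i0[!in_gap]; i1 <- i1[!in_gap]; gap <- gap[!in_gap]; exact <- exact[!in_gap]
  u <- ifelse(exact, 0, (g$t_s - t_h[i0]) / ifelse(gap == 0, 1, gap))
  P0 <- as.matrix(head[i0, c("px_m", "py_m", "pz_m")])
  P1 <- as.matrix(head[i1, c("px_m", "py_m", "pz_m")])
  Q0 <- as.matrix(head[i0, c("qw", "qx", "qy", "qz")])
  Q1 <- as.matrix(head[i1, c("qw", "qx", "qy", "qz")])
  P <- P0 * (1 - u) + P1 * u
  Q <- slerp_rows(Q0, Q1, u)
  D <- quat_rotate(Q, as.matrix(g[, c("gx", "gy", "gz")]))
  out <- data.frame(t_s = g$t_s, px_m = P[, 1], py_m = P[, 2], pz_m = P[, 3],
                    qw = Q[, 1], qx = Q[, 2], qy = Q[, 3], qz = Q[, 4],
                    dx = D[, 1], dy = D[, 2], dz = D[, 3])
  attr(out, "dropped") <- c(out_of_span = n_out_span, head_gap = n_gap,
                            invalid = sum(gaze$valid == 0))
  out
}
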