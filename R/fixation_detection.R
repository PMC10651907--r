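# I-VT fixation detection on the synchronized stream. A fixation is a maximal
# run of samples whose angular velocity stays below the threshold (30 deg/s).
# Velocity is computed on world-frame gaze directions by default so that
# smooth head translation while fixating a static object (VOR-like behavior)
# still registers as a fixation; head-frame mode is available via `frame`.

#' Fixation detector configuration
#'
#' @param velocity_threshold deg/s; samples below it are fixation candidates.
#' @param min_duration seconds; shorter runs are discarded. 60 ms is the
#'   standard I-VT event-treatment value.
#' @param max_gap seconds; two runs separated by at most this gap are merged
#'   when their mean directions agree within `merge_angle`.
#' @param merge_angle degrees; angular-consistency bound for merging, so that
#'   pre- and post-saccade fixations are never fused.
#' @param frame `"world"` or `"head"`: the frame in which angular velocity is
#'   estimated.
#' @export
detector_config <- function(velocity_threshold = 30, min_duration = 0.060,
                            max_gap = 0.075, merge_angle = 0.5,
                            frame = c("world", "head")) {
  if (velocity_threshold <= 0) stop_invalid("velocity threshold must be > 0")
  if (min_duration < 0 || max_gap < 0) stop_invalid("durations must be >= 0")
  list(velocity_threshold = velocity_threshold, min_duration = min_duration,
       max_gap = max_gap, merge_angle = merge_angle, frame = match.arg(frame))
}

#' Detect fixations in a synchronized gaze stream
#'
#' @param synced output of [synchronize()].
#' @param cfg a [detector_config()].
#' @return data frame of fixations, time-ordered and non-overlapping, with
#'   columns `t_start_s`, `t_end_s`, `duration_s`, `ox, oy, oz` (mean ray
#'   origin), `dx, dy, dz` (renormalized mean ray direction), `n_samples`,
#'   `label` (all `"unassigned"`).
#' @export
detect_fixations <- function(synced, cfg = detector_config()) {
  n <- nrow(synced)
  if (is.null(n) || n < 2L) stop_invalid("fixation detection needs at least 2 samples")
  ts <- synced$t_s
  dirs <- as.matrix(synced[, c("dx", "dy", "dz")])
  if (cfg$frame == "head") {
    Q <- as.matrix(synced[, c("qw", "qx", "qy", "qz")])
    dirs <- quat_rotate(quat_conjugate(Q), dirs)
  }
  v <- angular_velocity_series(dirs, ts)
  fixsamp <- v < cfg$velocity_threshold
  r <- rle(fixsamp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(empty_fixations())
  origins <- as.matrix(synced[, c("px_m", "py_m", "pz_m")])

  run_dir <- function(a, b) unit3(colMeans(dirs[a:b, , drop = FALSE]))
  merged <- list()
  cur <- c(runs$start[1], runs$end[1])
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- ts[runs$start[i]] - ts[cur[2]]
      if (gap <= cfg$max_gap &&
          angle_between_deg(run_dir(cur[1], cur[2]),
                            run_dir(runs$start[i], runs$end[i])) <= cfg$merge_angle) {
        cur[2] <- runs$end[i]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- c(runs$start[i], runs$end[i])
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur

  rows <- lapply(merged, function(se) {
    a <- se[1]; b <- se[2]
    dur <- ts[b] - ts[a]
    if (dur < cfg$min_duration) return(NULL)
    idx <- seq(a, b)
    idx <- idx[fixsamp[idx]] # mean ray over sub-threshold samples only
    o <- colMeans(origins[idx, , drop = FALSE])
    d <- unit3(colMeans(dirs[idx, , drop = FALSE]))
    data.frame(t_start_s = ts[a], t_end_s = ts[b], duration_s = dur,
               ox = o[1], oy = o[2], oz = o[3], dx = d[1], dy = d[2], dz = d[3],
               n_samples = length(idx), label = "unassigned",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_fixations())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
empty_fixations <- function() {
  data.frame(t_start_s = numeric(0), t_end_s = numeric(0), duration_s = numeric(0),
             ox = numeric(0), oy = numeric(0), oz = numeric(0),
             dx = numeric(0), dy = numeric(0), dz = numeric(0),
             n_samples = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Write detected fixations to CSV
#' @param fixations fixation data frame.
#' @param path output path.
#' @export
write_fixations_csv <- function(fixations, path) {
  utils::write.csv(fixations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
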