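# Synthetic experiment generator: factorial design, stimulus pairs, and an
# agent that walks and looks, emitting noisy 120 Hz head-pose and 50 Hz gaze
# streams with complete ground truth.
#
# The scanpath is scheduled on the 20 ms gaze grid as a sequence of fixation
# events (object inspections, environment glances, walking segments during
# which the agent fixates a floor point ahead) joined by saccade-like
# transitions. Transition direction profiles are constructed so that, in the
# noiseless case, every sample of a scheduled fixation sits strictly below the
# 30 deg/s velocity threshold and every transition sample sits strictly above
# it (including the central-difference samples straddling the boundary), so
# the detector recovers the scheduled events exactly.
#
# Gaze noise is decomposed into a per-trial systematic offset (calibration
# error, the dominant term in a mobile tracker's "mean accuracy") plus small
# per-sample jitter (precision), with the scales set so the overall mean
# angular error equals the target (default 1.42 deg).

#' Behavioral and scene parameters of the simulator
#'
#' Defaults encode the study conditions: 120/50 Hz sampling, a 3.4 x 4.3 m
#' arena, two post-mounted stimuli, per-complexity mean fixation counts and
#' accuracies, a categorical fixation-grouping distribution, 1.42 deg mean
#' gaze error and 0.2 mm per-axis head-position noise. Start positions: in
#' line with both posts (`P_s`), on the perpendicular bisector (`P_l`), and
#' oblique (`P_c`); only the topology is fixed, coordinates are configurable.
#'
#' @param ... named overrides of any default listed in the function body.
#' @return named list of parameters.
#' @export
behavior_params <- function(...) {
  p <- list(
    gaze_hz = 50, head_hz = 120,
    arena = c(3.4, 4.3),
    mounts = list(c(1.5, 2.6, 1.2), c(1.9, 2.6, 1.2)),
    eye_height = 1.6,
    start_positions = list(P_s = c(0.5, 2.6), P_l = c(1.7, 0.1), P_c = c(0.144, 1.044)),
    walk_speed = 0.8,
    head_limits_deg = c(pitch = 60, roll = 40, yaw = 70),
    eye_limits_deg = c(horizontal = 40, vertical = 40),
    fix_median_s = 0.30, fix_sdlog = 0.35, fix_max_s = 1.2, fix_min_samples = 8L,
    fix_count_mean = c(C_e = 76.56, C_m = 79.53, C_h = 121.06),
    fix_count_sdlog = 0.30, min_fixations = 6L,
    grouping_probs = c(18.70, 18.43, 12.26, 8.57, 6.71, 4.87, 3.74, 3.23, 18.41) /
      sum(c(18.70, 18.43, 12.26, 8.57, 6.71, 4.87, 3.74, 3.23, 18.41)),
    higher_sizes = 9:12,
    p_env_glance = 0.15, p_move = 0.30,
    glance_median_s = 0.35,
    accuracy = c(C_e = 0.961, C_m = 0.9418, C_h = 0.912),
    answer_delay_s = 1.0,
    hold_s = 0.4,
    walk_lookahead_m = 2.0,
    jitter_frac = 0.4,       # fixation targets within this fraction of the bounding radius
    min_sep_deg = 2.0,       # minimal angular separation of consecutive fixation targets
    vantage_radius_range = c(0.9, 1.35),
    vantage_azimuth_deg = c(50, 130),
    tau_head_s = 0.08,
    noise = TRUE,
    gaze_mean_err_deg = 1.42, gaze_jitter_sd_deg = 0.12,
    head_pos_sd_m = 2e-4, p_invalid = 0.005,
    max_trial_s = 240
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop_invalid("unknown behavior parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' Load behavior parameters from a YAML file
#'
#' The file holds named overrides of [behavior_params()] defaults (unknown
#' names are rejected); an empty or absent mapping returns the defaults.
#'
#' @param path YAML file path.
#' @export
behavior_params_from_yaml <- function(path) {
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) return(behavior_params())
  def <- behavior_params()
  ov <- lapply(stats::setNames(names(ov), names(ov)), function(nm) {
    x <- ov[[nm]]
    if (is.list(x) && !is.null(def[[nm]]) && !is.list(def[[nm]])) {
      unlist(x) # YAML mappings/sequences for atomic numeric parameters
    } else if (is.list(x) && is.list(def[[nm]])) {
      lapply(x, unlist)
    } else x
  })
  do.call(behavior_params, ov)
}

#' Generate the factorial experiment design
#'
#' Complexity is balanced within subject (`n_trials/3` trials per level, in
#' random order); start position, orientation difference and sameness are
#' uniform random per trial.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject; must be divisible by 3.
#' @param seed optional RNG seed.
#' @return data frame of trial skeletons (`subject_id`, `trial_index`,
#'   `complexity`, `start_position`, `orientation_diff_deg`, `same`).
#' @export
generate_design <- function(n_subjects = 47L, n_trials = 18L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_trials %% 3 != 0) stop_invalid("n_trials must be divisible by 3")
  per <- n_trials / 3
  rows <- lapply(seq_len(n_subjects), function(s) {
    data.frame(
      subject_id = sprintf("S%02d", s),
      trial_index = seq_len(n_trials),
      complexity = sample(rep(c("C_e", "C_m", "C_h"), per)),
      start_position = sample(c("P_l", "P_s", "P_c"), n_trials, replace = TRUE),
      orientation_diff_deg = sample(c(0, 90, 180), n_trials, replace = TRUE),
      same = sample(c(TRUE, FALSE), n_trials, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# ---- transition planning ---------------------------------------------------

#' @keywords internal
# Step-angle profile (degrees) for a saccade-like transition of total angle
# gamma, built so boundary central-difference samples classify correctly:
# first step < 1.2 deg (the last fixation sample stays below threshold), all
# interior pair sums and the landing step >= 1.3 deg (every transition sample
# stays above threshold with margin).
transition_steps <- function(gamma) {
  if (gamma < 1.9) stop_invalid("transition angle below the plannable minimum")
  if (gamma <= 3.0) return(c(0.6, gamma - 0.6))
  m <- max(1L, ceiling((gamma - 2.0) / 4.5))
  c(0.6, rep((gamma - 2.0) / m, m), 1.4)
}

#' @keywords internal
slerp_dir <- function(a, b, f) {
  d <- min(max(sum(a * b), -1), 1)
  ang <- acos(d)
  if (ang < 1e-9) return(matrix(b, length(f), 3, byrow = TRUE))
  (outer(sin((1 - f) * ang), a) + outer(sin(f * ang), b)) / sin(ang)
}

#' @keywords internal
perp_dir <- function(a) {
  e <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit3(cross3(matrix(a, 1), matrix(e, 1))[1, ])
}

#' @keywords internal
# World directions of the transition samples between two fixation directions.
# Angles below the plannable minimum are routed through a 4 deg via-point.
transition_dirs <- function(a, b) {
  gamma <- angle_between_deg(a, b)
  if (gamma >= 1.9) {
    s <- transition_steps(gamma)
    return(slerp_dir(a, b, cumsum(s) / gamma))
  }
  w <- unit3(cos(4 * pi / 180) * a + sin(4 * pi / 180) * perp_dir(a))
  s1 <- transition_steps(4)
  d1 <- slerp_dir(a, w, cumsum(s1) / 4)
  g2 <- angle_between_deg(w, b)
  s2 <- transition_steps(g2)
  d2 <- slerp_dir(w, b, cumsum(s2) / g2)
  rbind(d1, d2)
}

# ---- trial simulation ------------------------------------------------------

#' @keywords internal
sample_vantage <- function(mid_xy, params) {
  az_rng <- params$vantage_azimuth_deg
  az <- stats::runif(1, az_rng[1], az_rng[2]) * sample(c(1, -1), 1)
  r <- stats::runif(1, params$vantage_radius_range[1], params$vantage_radius_range[2])
  xy <- mid_xy + r * c(cos(az * pi / 180), sin(az * pi / 180))
  xy[1] <- min(max(xy[1], 0.2), params$arena[1] - 0.2)
  xy[2] <- min(max(xy[2], 0.2), params$arena[2] - 0.2)
  c(xy, params$eye_height)
}

#' @keywords internal
sample_fix_samples <- function(median_s, sdlog, max_s, min_samples, dt) {
  d <- min(stats::rlnorm(1, log(median_s), sdlog), max_s)
  max(min_samples, round(d / dt) + 1L)
}

#' @keywords internal
# Jitter target inside the object bounding sphere, resampled for angular
# separation from the previous gaze direction.
sample_object_target <- function(center, radius, pos, prev_dir, params) {
  for (i in 1:80) {
    v <- stats::rnorm(3)
    off <- v / sqrt(sum(v^2)) * radius * params$jitter_frac * stats::runif(1)^(1 / 3)
    pt <- center + off
    d <- unit3(pt - pos)
    if (is.null(prev_dir) || angle_between_deg(d, prev_dir) >= params$min_sep_deg) return(pt)
  }
  pt
}

#' @keywords internal
fix_event <- function(label, obj, target, p0, p1, n_samp, anchor) {
  list(label = label, obj = obj, target = target, p0 = p0, p1 = p1,
       n_samp = as.integer(n_samp), anchor = anchor)
}

#' @keywords internal
# Minimal angular miss (deg, beyond the sphere limb) of gaze rays from points
# along a walk toward a candidate floor point, over both objects.
walk_clearance <- function(from, to, pt, ctr, rad) {
  fr <- seq(0, 1, length.out = 15)
  P <- outer(1 - fr, from) + outer(fr, to)
  M <- sweep(-P, 2, pt, "+")
  D <- M / sqrt(rowSums(M^2))
  mins <- vapply(1:2, function(o) {
    C <- sweep(-P, 2, ctr[[o]], "+")
    dist <- sqrt(rowSums(C^2))
    ang <- angle_between_deg(D, C / dist)
    min(ang - asin(pmin(rad[o] / dist, 1)) * 180 / pi)
  }, numeric(1))
  min(mins)
}

#' @keywords internal
# Walking segment scheduled as one environment fixation: the agent fixates a
# floor point ahead of the destination, laterally offset away from the posts
# when needed so the walking gaze keeps angular clearance from both objects.
walk_event <- function(from, to, ctr, rad, mid_xy, params, dt) {
  dist <- sqrt(sum((to - from)^2))
  u_xy <- (to[1:2] - from[1:2]) / max(sqrt(sum((to[1:2] - from[1:2])^2)), 1e-9)
  n_perp <- c(-u_xy[2], u_xy[1])
  if (sum(n_perp * (mid_xy - to[1:2])) > 0) n_perp <- -n_perp
  best <- NULL; best_clr <- -Inf
  for (la in c(params$walk_lookahead_m, 1.2)) {
    for (off in c(0, 0.8, 1.4, 2.0)) {
      pt <- c(to[1:2] + la * u_xy + off * n_perp, 0)
      clr <- walk_clearance(from, to, pt, ctr, rad)
      if (clr > best_clr) { best <- pt; best_clr <- clr }
      if (clr >= 4) break
    }
    if (best_clr >= 4) break
  }
  n <- max(10L, ceiling(dist / params$walk_speed / dt) + 1L)
  fix_event("environment", 0L, best, from, to, n, best)
}

#' @keywords internal
gaze_noise_scales <- function(mean_err_deg, jitter_sd_deg) {
  sigma_total <- mean_err_deg / sqrt(pi / 2)
  c(offset = sqrt(max(sigma_total^2 - jitter_sd_deg^2, 0)), jitter = jitter_sd_deg)
}

#' @keywords internal
# Rotate each row of D by a tangent-plane perturbation (e1, e2 degrees); the
# angular deviation of row i equals sqrt(e1^2 + e2^2) exactly.
perturb_dirs <- function(D, e1_deg, e2_deg) {
  z <- matrix(c(0, 0, 1), nrow(D), 3, byrow = TRUE)
  b1 <- cross3(D, z)
  n1 <- sqrt(rowSums(b1^2))
  deg <- n1 < 1e-6
  if (any(deg)) {
    alt <- cross3(D[deg, , drop = FALSE], matrix(c(0, 1, 0), sum(deg), 3, byrow = TRUE))
    b1[deg, ] <- alt
    n1[deg] <- sqrt(rowSums(alt^2))
  }
  b1 <- b1 / n1
  b2 <- cross3(D, b1)
  rho <- sqrt(e1_deg^2 + e2_deg^2) * pi / 180
  u <- (b1 * e1_deg + b2 * e2_deg) / ifelse(rho > 0, rho * 180 / pi, 1)
  cos(rho) * D + sin(rho) * u
}

#' @keywords internal
# Vectorized look-at: rows of F are forward (+x) directions; up kept near
# world +z. Rotation matrices [f l u] are converted to quaternions with the
# standard four-branch extraction, applied rowwise.
look_at_rows <- function(F) {
  F <- F / sqrt(rowSums(F^2))
  up <- matrix(c(0, 0, 1), nrow(F), 3, byrow = TRUE)
  vert <- abs(F[, 3]) > 1 - 1e-9
  up[vert, ] <- rep(c(0, 1, 0), each = sum(vert))
  L <- cross3(up, F)
  L <- L / sqrt(rowSums(L^2))
  U <- cross3(F, L)
  # R = [f l u] columns
  r11 <- F[, 1]; r21 <- F[, 2]; r31 <- F[, 3]
  r12 <- L[, 1]; r22 <- L[, 2]; r32 <- L[, 3]
  r13 <- U[, 1]; r23 <- U[, 2]; r33 <- U[, 3]
  tr <- r11 + r22 + r33
  n <- length(tr)
  Q <- matrix(0, n, 4)
  b0 <- tr > 0
  if (any(b0)) {
    s <- 2 * sqrt(1 + tr[b0])
    Q[b0, ] <- cbind(s / 4, (r32[b0] - r23[b0]) / s, (r13[b0] - r31[b0]) / s,
                     (r21[b0] - r12[b0]) / s)
  }
  rest <- which(!b0)
  if (length(rest)) {
    dmax <- max.col(cbind(r11[rest], r22[rest], r33[rest]))
    i1 <- rest[dmax == 1]
    if (length(i1)) {
      s <- 2 * sqrt(1 + r11[i1] - r22[i1] - r33[i1])
      Q[i1, ] <- cbind((r32[i1] - r23[i1]) / s, s / 4, (r12[i1] + r21[i1]) / s,
                       (r13[i1] + r31[i1]) / s)
    }
    i2 <- rest[dmax == 2]
    if (length(i2)) {
      s <- 2 * sqrt(1 + r22[i2] - r11[i2] - r33[i2])
      Q[i2, ] <- cbind((r13[i2] - r31[i2]) / s, (r12[i2] + r21[i2]) / s, s / 4,
                       (r23[i2] + r32[i2]) / s)
    }
    i3 <- rest[dmax == 3]
    if (length(i3)) {
      s <- 2 * sqrt(1 + r33[i3] - r11[i3] - r22[i3])
      Q[i3, ] <- cbind((r21[i3] - r12[i3]) / s, (r13[i3] + r31[i3]) / s,
                       (r23[i3] + r32[i3]) / s, s / 4)
    }
  }
  Q <- Q / sqrt(rowSums(Q^2))
  flip <- Q[, 1] < 0
  Q[flip, ] <- -Q[flip, , drop = FALSE]
  Q
}

#' @keywords internal
# Exponential pursuit smoothing of a direction series (recursive filter per
# axis, renormalized at the end; the norm floor guards near-antipodal swings).
smooth_dirs <- function(D, alpha) {
  out <- vapply(1:3, function(k) {
    as.numeric(stats::filter(alpha * D[, k], 1 - alpha, method = "recursive",
                             init = D[1, k]))
  }, numeric(nrow(D)))
  out / pmax(sqrt(rowSums(out^2)), 1e-3)
}

#' Simulate one trial
#'
#' The agent starts at the configured start position facing the curtain,
#' turns, walks to a vantage point, and executes an inspection itinerary:
#' group sizes drawn from the grouping distribution with strictly alternating
#' target objects, occasional environment glances, and walks between vantage
#' points (fixating a floor point ahead while walking). Fixation durations are
#' log-normal. Kinematics are emitted noiselessly and noise is injected
#' afterwards, so ground truth logs every scheduled event.
#'
#' @param record one trial skeleton (row of [generate_design()] as a list or
#'   one-row data frame).
#' @param params a [behavior_params()] list.
#' @param seed optional RNG seed for the trial.
#' @param instances optional pre-built stimulus pair (list of two
#'   `object_instance`); generated from the trial factors when `NULL`.
#' @param noise inject sensor noise? Defaults to `params$noise`.
#' @return list with `head` (120 Hz stream), `gaze` (50 Hz stream),
#'   `instances`, `record` (completed with `answer`, `answer_time_s`), and
#'   `truth` (scheduled fixation table, per-label counts, response time, head
#'   path length, group sizes, correctness).
#' @export
simulate_trial <- function(record, params = behavior_params(), seed = NULL,
                           instances = NULL, noise = params$noise) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / params$gaze_hz
  if (is.null(instances)) {
    instances <- make_stimulus_pair(record$complexity, record$same,
                                    record$orientation_diff_deg, mounts = params$mounts)
  }
  ctr <- list(instances[[1]]$center, instances[[2]]$center)
  rad <- c(instances[[1]]$bounding_radius, instances[[2]]$bounding_radius)
  mid_xy <- (ctr[[1]][1:2] + ctr[[2]][1:2]) / 2
  start_xy <- params$start_positions[[record$start_position]]
  p_start <- c(start_xy, params$eye_height)

  # --- itinerary ------------------------------------------------------------
  target_n <- max(params$min_fixations,
                  round(stats::rlnorm(1, log(params$fix_count_mean[[record$complexity]]),
                                      params$fix_count_sdlog)))
  sizes <- integer(0); tot <- 0L
  while (tot < target_n) {
    k <- sample.int(9L, 1L, prob = params$grouping_probs)
    g <- if (k == 9L) sample(params$higher_sizes, 1L) else k
    sizes <- c(sizes, g); tot <- tot + g
  }
  first_obj <- sample.int(2L, 1L)
  objs <- rep_len(c(first_obj, 3L - first_obj), length(sizes))

  # --- event list (fixations only; transitions inserted at assembly) -------
  events <- list()
  hold_target <- p_start + c(0, -3, 0) # facing the curtain
  events[[1L]] <- fix_event("environment", 0L, hold_target, p_start, p_start,
                            max(params$fix_min_samples, round(params$hold_s / dt) + 1L),
                            hold_target)
  pos <- sample_vantage(mid_xy, params)
  events[[2L]] <- walk_event(p_start, pos, ctr, rad, mid_xy, params, dt)

  max_samples <- ceiling(params$max_trial_s / dt)
  n_scheduled <- sum(vapply(events, `[[`, integer(1), "n_samp"))
  truncated <- FALSE
  prev_dir <- NULL
  realized_sizes <- integer(0)
  for (gi in seq_along(sizes)) {
    if (n_scheduled > max_samples) { truncated <- TRUE; break }
    o <- objs[gi]
    for (j in seq_len(sizes[gi])) {
      pt <- sample_object_target(ctr[[o]], rad[o], pos, prev_dir, params)
      n <- sample_fix_samples(params$fix_median_s, params$fix_sdlog,
                              params$fix_max_s, params$fix_min_samples, dt)
      events[[length(events) + 1L]] <- fix_event(paste0("object", o), o, pt, pos, pos,
                                                 n, ctr[[o]])
      prev_dir <- unit3(pt - pos)
      n_scheduled <- n_scheduled + n
    }
    realized_sizes <- c(realized_sizes, sizes[gi])
    if (gi < length(sizes)) {
      if (stats::runif(1) < params$p_env_glance) {
        gpt <- c(mid_xy + stats::runif(2, -0.4, 0.4), 0)
        n <- sample_fix_samples(params$glance_median_s, params$fix_sdlog,
                                params$fix_max_s, params$fix_min_samples, dt)
        events[[length(events) + 1L]] <- fix_event("environment", 0L, gpt, pos, pos, n, gpt)
        prev_dir <- unit3(gpt - pos)
        n_scheduled <- n_scheduled + n
      }
      if (stats::runif(1) < params$p_move) {
        nv <- sample_vantage(mid_xy, params)
        events[[length(events) + 1L]] <- walk_event(pos, nv, ctr, rad, mid_xy, params, dt)
        prev_dir <- NULL # walk end direction is computed at assembly
        pos <- nv
        n_scheduled <- n_scheduled + events[[length(events)]]$n_samp
      }
    }
  }
  if (truncated) warning("trial itinerary truncated at max_trial_s")

  # --- assemble gaze-grid samples ------------------------------------------
  dir_blocks <- list(); pos_blocks <- list(); anchor_rows <- list(); seg_start <- numeric(0)
  tr_start <- tr_end <- numeric(length(events))
  tr_label <- character(length(events)); tr_obj <- integer(length(events))
  idx <- 0L
  cur_dir <- NULL
  for (ei in seq_along(events)) {
    e <- events[[ei]]
    d_start <- unit3(e$target - e$p0)
    d_end <- unit3(e$target - e$p1)
    if (!is.null(cur_dir)) {
      td <- transition_dirs(cur_dir, d_start)
      dir_blocks[[length(dir_blocks) + 1L]] <- td
      pos_blocks[[length(pos_blocks) + 1L]] <- matrix(e$p0, nrow(td), 3, byrow = TRUE)
      anchor_rows[[length(anchor_rows) + 1L]] <- matrix(e$anchor, 1)
      seg_start <- c(seg_start, idx * dt)
      idx <- idx + nrow(td)
    }
    n <- e$n_samp
    if (any(e$p0 != e$p1)) {
      fr <- seq(0, 1, length.out = n)
      P <- outer(1 - fr, e$p0) + outer(fr, e$p1)
      M <- sweep(-P, 2, e$target, "+")
      D <- M / sqrt(rowSums(M^2))
    } else {
      P <- matrix(e$p0, n, 3, byrow = TRUE)
      D <- matrix(d_start, n, 3, byrow = TRUE)
    }
    dir_blocks[[length(dir_blocks) + 1L]] <- D
    pos_blocks[[length(pos_blocks) + 1L]] <- P
    anchor_rows[[length(anchor_rows) + 1L]] <- matrix(e$anchor, 1)
    seg_start <- c(seg_start, idx * dt)
    tr_start[ei] <- idx * dt; tr_end[ei] <- (idx + n - 1L) * dt
    tr_label[ei] <- e$label; tr_obj[ei] <- e$obj
    idx <- idx + n
    cur_dir <- d_end
  }
  Dw <- do.call(rbind, dir_blocks)
  P <- do.call(rbind, pos_blocks)
  A <- do.call(rbind, anchor_rows)
  N <- nrow(Dw)
  tg <- (seq_len(N) - 1) * dt
  truth_fix <- data.frame(t_start_s = tr_start, t_end_s = tr_end,
                          label = tr_label, object = tr_obj, stringsAsFactors = FALSE)

  # --- head stream at 120 Hz ------------------------------------------------
  Nh <- ceiling(tg[N] * params$head_hz) + 1L
  th <- (seq_len(Nh) - 1) / params$head_hz
  Ph <- cbind(stats::approx(tg, P[, 1], th, rule = 2)$y,
              stats::approx(tg, P[, 2], th, rule = 2)$y,
              stats::approx(tg, P[, 3], th, rule = 2)$y)
  seg <- pmin(findInterval(th, seg_start), nrow(A))
  tgt <- A[seg, , drop = FALSE] - Ph
  Ft <- tgt / sqrt(rowSums(tgt^2))
  alpha <- 1 - exp(-(1 / params$head_hz) / params$tau_head_s)
  Fh <- smooth_dirs(smooth_dirs(Ft, alpha), alpha)
  Qh <- look_at_rows(Fh)

  # --- gaze stream: head pose interpolated to gaze times, then inverted -----
  i0 <- pmax(pmin(findInterval(tg, th), Nh - 1L), 1L)
  u <- (tg - th[i0]) * params$head_hz
  Qg <- slerp_rows(Qh[i0, , drop = FALSE], Qh[i0 + 1L, , drop = FALSE], u)
  dir_head <- quat_rotate(quat_conjugate(Qg), Dw)

  # --- ground truth ---------------------------------------------------------
  answer_time <- tg[N] + params$answer_delay_s
  correct <- stats::runif(1) < params$accuracy[[record$complexity]]
  truth_ans <- if (isTRUE(as.logical(record$same))) "same" else "different"
  answer <- if (correct) truth_ans else setdiff(c("same", "different"), truth_ans)
  truth <- list(
    fixations = truth_fix,
    n_fix_obj1 = sum(truth_fix$label == "object1"),
    n_fix_obj2 = sum(truth_fix$label == "object2"),
    n_fix_env = sum(truth_fix$label == "environment"),
    response_time_s = answer_time - truth_fix$t_start_s[1],
    head_path_m = sum(sqrt(rowSums(diff(Ph)^2))),
    group_sizes = realized_sizes,
    answer = answer, correct = correct, answer_time_s = answer_time,
    truncated = truncated
  )

  # --- noise injection ------------------------------------------------------
  valid <- rep(1L, N)
  if (noise) {
    Ph <- Ph + matrix(stats::rnorm(3 * Nh, 0, params$head_pos_sd_m), Nh, 3)
    sc <- gaze_noise_scales(params$gaze_mean_err_deg, params$gaze_jitter_sd_deg)
    off <- stats::rnorm(2, 0, sc["offset"])
    dir_head <- perturb_dirs(dir_head,
                             off[1] + stats::rnorm(N, 0, sc["jitter"]),
                             off[2] + stats::rnorm(N, 0, sc["jitter"]))
    valid <- stats::rbinom(N, 1, 1 - params$p_invalid)
  }

  rec <- as.list(record)
  rec$answer <- answer
  rec$answer_time_s <- answer_time
  list(
    head = data.frame(t_s = th, px_m = Ph[, 1], py_m = Ph[, 2], pz_m = Ph[, 3],
                      qw = Qh[, 1], qx = Qh[, 2], qy = Qh[, 3], qz = Qh[, 4]),
    gaze = data.frame(t_s = tg, gx = dir_head[, 1], gy = dir_head[, 2],
                      gz = dir_head[, 3], valid = valid),
    instances = instances, record = rec, truth = truth
  )
}

#' Simulate a full experiment to disk
#'
#' Writes one sub-directory per trial (`head.csv`, `gaze.csv`,
#' `object1.json`, `object2.json`, `trial.json`) plus a `manifest.json`
#' linking ground truth to the files. Fully reproducible from the seed.
#'
#' @param design data frame from [generate_design()].
#' @param params a [behavior_params()] list.
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed; per-trial sub-seeds are derived from it.
#' @return the manifest, invisibly.
#' @export
simulate_experiment <- function(design, params = behavior_params(), out_dir, seed = 1L) {
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, nrow(design))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    rec <- as.list(design[i, ])
    td <- file.path(out_dir, sprintf("%s_trial%02d", rec$subject_id, rec$trial_index))
    dir.create(td, showWarnings = FALSE)
    sim <- simulate_trial(rec, params, seed = trial_seeds[i])
    write_head_csv(sim$head, file.path(td, "head.csv"))
    write_gaze_csv(sim$gaze, file.path(td, "gaze.csv"))
    write_object_json(sim$instances[[1]], file.path(td, "object1.json"))
    write_object_json(sim$instances[[2]], file.path(td, "object2.json"))
    write_trial_json(sim$record, file.path(td, "trial.json"))
    manifest[[i]] <- list(
      dir = basename(td), subject_id = rec$subject_id, trial_index = rec$trial_index,
      seed = trial_seeds[i],
      truth = sim$truth[c("n_fix_obj1", "n_fix_obj2", "n_fix_env", "response_time_s",
                          "head_path_m", "group_sizes", "answer", "correct",
                          "answer_time_s", "truncated")]
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
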