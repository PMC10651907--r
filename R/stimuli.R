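# Polycube stimuli: block-built objects on a cubic lattice, compared for
# "sameness" by geometric congruence under the 24 proper lattice rotations.
# Mirror images count as different: the stimuli are rigid physical objects and
# a chiral pair is visually distinguishable.

COMPLEXITY_BLOCKS <- c(C_e = 7L, C_m = 10L, C_h = 18L)

#' The 24 proper rotation matrices of the cubic lattice
#' @return list of 3 x 3 integer matrices with determinant +1.
#' @export
lattice_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
      R <- matrix(0, 3, 3)
      R[1, p[1]] <- sx; R[2, p[2]] <- sy; R[3, p[3]] <- sz
      if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1L]] <- R
    }
  }
  stopifnot(length(out) == 24L)
  out
}

#' @keywords internal
cells_connected <- function(cells) {
  n <- nrow(cells)
  if (n == 1L) return(TRUE)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  idx <- stats::setNames(seq_len(n), key(cells))
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    cand <- sweep(nb, 2, cells[i, ], "+")
    hits <- idx[key(cand)]
    hits <- hits[!is.na(hits)]
    new <- hits[!seen[hits]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Construct a polycube stimulus object
#'
#' @param cells n x 3 integer matrix of lattice cell coordinates; must be
#'   face-connected (6-connectivity) and duplicate-free.
#' @param cell_size edge length of one block, meters. The 0.03 m default puts
#'   an 18-block object in the rough 12 x 14 x 18 cm envelope of the physical
#'   set.
#' @return a `polycube` list with fields `cells`, `n`, `complexity`
#'   (`C_e`/`C_m`/`C_h` for n = 7/10/18, `NA` otherwise) and `cell_size`.
#' @export
polycube <- function(cells, cell_size = 0.03) {
  cells <- as_row_matrix(cells, 3L)
  storage.mode(cells) <- "integer"
  if (anyDuplicated(paste(cells[, 1], cells[, 2], cells[, 3]))) {
    stop_invalid("polycube cells must be unique")
  }
  if (!cells_connected(cells)) stop_invalid("polycube cells must be face-connected")
  n <- nrow(cells)
  cx <- names(COMPLEXITY_BLOCKS)[match(n, COMPLEXITY_BLOCKS)]
  structure(list(cells = cells, n = n, complexity = cx, cell_size = cell_size),
            class = "polycube")
}

#' Canonical form of a polycube cell set
#'
#' Translates the cells to the origin and returns the lexicographically
#' minimal sorted cell list over the 24 proper lattice rotations. Two
#' polycubes are congruent (proper rotations only) iff their canonical forms
#' are identical.
#'
#' @param cells n x 3 integer matrix of connected lattice cells.
#' @return n x 3 integer matrix, sorted rows, min coordinate 0 on each axis.
#' @export
canonical_form <- function(cells) {
  cells <- as_row_matrix(cells, 3L)
  if (!cells_connected(cells)) stop_invalid("canonical_form requires connected cells")
  best <- NULL
  for (R in lattice_rotations()) {
    r <- cells %*% t(R)
    r <- sweep(r, 2, apply(r, 2, min))
    r <- r[order(r[, 1], r[, 2], r[, 3]), , drop = FALSE]
    flat <- as.vector(t(r))
    if (is.null(best) || vec_less(flat, best_flat)) {
      best <- r; best_flat <- flat
    }
  }
  storage.mode(best) <- "integer"
  dimnames(best) <- NULL
  best
}

#' @keywords internal
vec_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' Are two polycubes congruent under proper rotations?
#'
#' @param a,b `polycube` objects.
#' @return `TRUE` iff the cell sets match under translation and one of the 24
#'   proper rotations. Mirror pairs are not congruent.
#' @export
are_congruent <- function(a, b) {
  if (a$n != b$n) return(FALSE)
  identical(canonical_form(a$cells), canonical_form(b$cells))
}

#' Grow a random polycube by face-adjacent accretion
#'
#' Starting from a single cell, repeatedly picks a uniformly random occupied
#' cell and a uniformly random free face neighbor. Uses R's global RNG;
#' seed with [set.seed()] for reproducibility.
#'
#' @param n number of blocks, `>= 1`.
#' @param cell_size block edge, meters.
#' @return a `polycube` with exactly `n` cells.
#' @export
generate_random_polycube <- function(n, cell_size = 0.03) {
  if (!is.numeric(n) || n < 1) stop_invalid("block count must be >= 1")
  n <- as.integer(n)
  cells <- matrix(0L, 1, 3)
  occupied <- new.env(parent = emptyenv())
  assign("0 0 0", TRUE, envir = occupied)
  nb <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
              c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  while (nrow(cells) < n) {
    i <- sample.int(nrow(cells), 1L)
    cand <- cells[i, ] + nb[sample.int(6L, 1L), ]
    k <- paste(cand, collapse = " ")
    if (!exists(k, envir = occupied, inherits = FALSE)) {
      assign(k, TRUE, envir = occupied)
      cells <- rbind(cells, cand)
    }
  }
  dimnames(cells) <- NULL
  polycube(cells, cell_size = cell_size)
}

#' Pose a polycube in the world
#'
#' The pose position is the mount point (top of the post): the model's
#' bottom-center anchor is placed there and rotated by the pose orientation.
#' The bounding sphere (center + radius) used for gaze-target assignment is
#' derived from the posed cell centroid.
#'
#' @param model a `polycube`.
#' @param pose a `pose6dof` (mount point + orientation).
#' @return an `object_instance` list with `model`, `pose`, `center` (world
#'   bounding-sphere center) and `bounding_radius` (meters).
#' @export
object_instance <- function(model, pose) {
  cs <- model$cell_size
  centers <- (model$cells + 0.5) * cs
  centroid <- colMeans(centers)
  anchor <- c((min(centers[, 1]) + max(centers[, 1])) / 2,
              (min(centers[, 2]) + max(centers[, 2])) / 2,
              min(centers[, 3]) - 0.5 * cs)
  offset <- centroid - anchor
  radius <- max(sqrt(rowSums(sweep(centers, 2, centroid)^2))) + cs * sqrt(3) / 2
  structure(list(model = model, pose = pose,
                 center = pose$p + quat_rotate(pose$q, offset),
                 bounding_radius = radius),
            class = "object_instance")
}

#' Orientation difference between two posed instances, degrees
#' @param a,b `object_instance` objects.
#' @export
orientation_difference <- function(a, b) {
  angular_difference(a$pose$q, b$pose$q)
}

#' Generate a posed stimulus pair for one trial
#'
#' Same pairs share one model; different pairs are rejection-sampled until the
#' two models fail [are_congruent()]. Both objects receive a common random
#' rotation about the vertical post axis; the second is additionally rotated
#' by `orientation_diff` about the same axis, so the measured orientation
#' difference equals the requested factor level.
#'
#' @param complexity one of `"C_e"`, `"C_m"`, `"C_h"`.
#' @param same logical; congruent pair?
#' @param orientation_diff degrees, one of 0, 90, 180.
#' @param mounts list of two length-3 mount points (post tops), meters.
#' @param max_tries rejection budget for the non-congruent model.
#' @return list of two `object_instance` objects.
#' @export
make_stimulus_pair <- function(complexity, same, orientation_diff,
                               mounts = list(c(1.5, 2.6, 1.2), c(1.9, 2.6, 1.2)),
                               max_tries = 100L) {
  if (!complexity %in% names(COMPLEXITY_BLOCKS)) stop_invalid("unknown complexity level")
  if (!orientation_diff %in% c(0, 90, 180)) stop_invalid("orientation_diff must be 0, 90 or 180")
  n <- COMPLEXITY_BLOCKS[[complexity]]
  m1 <- generate_random_polycube(n)
  if (same) {
    m2 <- m1
  } else {
    m2 <- NULL
    for (i in seq_len(max_tries)) {
      cand <- generate_random_polycube(n)
      if (!are_congruent(m1, cand)) { m2 <- cand; break }
    }
    if (is.null(m2)) {
      stop(errorCondition("could not generate a non-congruent pair within the retry budget",
                          class = c("activegaze_generation_error", "error")))
    }
  }
  alpha <- stats::runif(1, 0, 360)
  q1 <- quat_from_axis_angle(c(0, 0, 1), alpha)
  q2 <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), orientation_diff), q1)
  list(object_instance(m1, pose6dof(0, mounts[[1]], q1)),
       object_instance(m2, pose6dof(0, mounts[[2]], q2)))
}

#' Write / read a polycube model (and optional pose) as JSON
#' @param x a `polycube` or `object_instance`.
#' @param path file path.
#' @export
write_object_json <- function(x, path) {
  if (inherits(x, "object_instance")) {
    obj <- list(cells = unname(x$model$cells), cell_size_m = x$model$cell_size,
                complexity = x$model$complexity,
                pose = list(t = x$pose$t, position = x$pose$p, quaternion = x$pose$q))
  } else {
    obj <- list(cells = unname(x$cells), cell_size_m = x$cell_size,
                complexity = x$complexity)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_object_json
#' @export
read_object_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- polycube(obj$cells, cell_size = obj$cell_size_m)
  if (is.null(obj$pose)) return(model)
  object_instance(model, pose6dof(obj$pose$t, obj$pose$position, obj$pose$quaternion))
}
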