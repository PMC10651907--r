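# Per-trial dependent measures: response time, object-fixation counts,
# head-movement extent, primary/secondary fixation ratio, fixation grouping
# profile, correctness, and the complexity-normalized response time.

#' Response time of a trial
#'
#' Time elapsed from the first fixation of the trial to the moment the answer
#' was given.
#'
#' @param first_fix_start seconds (trial-relative).
#' @param answer_time seconds.
#' @export
response_time <- function(first_fix_start, answer_time) {
  if (!is.finite(first_fix_start) || !is.finite(answer_time)) {
    stop_invalid("response_time requires finite times")
  }
  if (answer_time <= first_fix_start) {
    stop_invalid("answer time must come after the first fixation")
  }
  answer_time - first_fix_start
}

#' Fixation grouping profile
#'
#' A grouping is a maximal run of consecutive fixations on one object before
#' focus shifts to the other object. Environment fixations are removed first
#' and, by default, do not split a run: an orientation glance at the floor
#' mid-inspection should not end an inspection episode (`split_on_environment
#' = TRUE` makes them split). Run lengths are tabulated into bins 1..8 and
#' "higher" (> 8); shares are percentages of the total number of runs.
#'
#' @param labels character vector over `object1`, `object2`, `environment`.
#' @param split_on_environment logical; see above.
#' @return list with `counts` (9 bins), `shares` (percent, sum 100 when any
#'   run exists), `n_runs`, `n_object_fixations`, `run_lengths`.
#' @export
grouping_profile <- function(labels, split_on_environment = FALSE) {
  stopifnot(all(labels %in% c("object1", "object2", "environment")))
  if (split_on_environment) {
    r <- rle(labels)
    lens <- r$lengths[r$values != "environment"]
  } else {
    obj <- labels[labels != "environment"]
    lens <- if (length(obj)) rle(obj)$lengths else integer(0)
  }
  bins <- c(as.character(1:8), "higher")
  counts <- stats::setNames(integer(9), bins)
  if (length(lens)) {
    tab <- table(factor(ifelse(lens > 8, "higher", as.character(lens)), levels = bins))
    counts[] <- as.integer(tab)
  }
  n_runs <- length(lens)
  shares <- if (n_runs > 0) 100 * counts / n_runs else stats::setNames(numeric(9), bins)
  list(counts = counts, shares = shares, n_runs = n_runs,
       n_object_fixations = sum(lens), run_lengths = as.integer(lens))
}

#' Primary/secondary fixation ratio
#'
#' Shares are over object fixations only. The object with the most fixations
#' is the primary object; an exact tie goes to the object fixated first
#' (deterministic and behaviorally motivated).
#'
#' @param labels character vector of fixation labels.
#' @return list `primary_share`, `secondary_share` (percent, summing to 100)
#'   and `primary_id` (`"object1"` or `"object2"`), or all-`NA` with a flag if
#'   no object fixation exists.
#' @export
fixation_ratio <- function(labels) {
  obj <- labels[labels %in% c("object1", "object2")]
  if (!length(obj)) {
    return(list(primary_share = NA_real_, secondary_share = NA_real_,
                primary_id = NA_character_, flagged = "no object fixations"))
  }
  n1 <- sum(obj == "object1"); n2 <- sum(obj == "object2")
  primary <- if (n1 > n2) "object1" else if (n2 > n1) "object2" else obj[1]
  np <- max(n1, n2); ns <- min(n1, n2)
  list(primary_share = 100 * np / (np + ns),
       secondary_share = 100 * ns / (np + ns),
       primary_id = primary, flagged = "")
}

#' Normalized response time per block element
#'
#' Mean response time divided by the block count of the complexity level,
#' reported to 2 decimals (seconds per element).
#'
#' @param mean_rt mean response time, seconds.
#' @param n_blocks number of blocks in the stimulus, `>= 1`.
#' @export
normalized_response_time <- function(mean_rt, n_blocks) {
  if (!is.numeric(n_blocks) || n_blocks < 1) stop_invalid("n_blocks must be >= 1")
  round(mean_rt / n_blocks, 2)
}

#' All per-trial measures from labeled fixations and the head stream
#'
#' Sub-metric failures (no fixations, no object fixations) are reported in the
#' `flagged` column, never by dropping the trial.
#'
#' @param record named list / one-row data frame of trial metadata
#'   (`subject_id`, `trial_index`, `complexity`, `start_position`,
#'   `orientation_diff_deg`, `same`, `answer`, `answer_time_s`).
#' @param fixations labeled fixation data frame.
#' @param head head stream data frame.
#' @param min_step noise floor for [path_length()], meters.
#' @return one-row data frame of trial metrics; the grouping profile is also
#'   attached as attribute `"grouping"`.
#' @export
summarize_trial <- function(record, fixations, head, min_step = 0.002) {
  truth <- if (isTRUE(as.logical(record$same))) "same" else "different"
  flagged <- character(0)
  rt <- NA_real_
  if (nrow(fixations) > 0L) {
    rt <- response_time(min(fixations$t_start_s), record$answer_time_s)
  } else {
    flagged <- c(flagged, "no fixations")
  }
  labels <- fixations$label
  ratio <- fixation_ratio(labels)
  if (nzchar(ratio$flagged)) flagged <- c(flagged, ratio$flagged)
  prof <- grouping_profile(labels)
  hp <- path_length(as.matrix(head[, c("px_m", "py_m", "pz_m")]), min_step = min_step)
  out <- data.frame(
    subject_id = record$subject_id, trial_index = record$trial_index,
    complexity = record$complexity, start_position = record$start_position,
    orientation_diff_deg = record$orientation_diff_deg,
    same = as.logical(record$same), answer = record$answer,
    correct = record$answer == truth,
    answer_time_s = record$answer_time_s, response_time_s = rt,
    n_fix_obj1 = sum(labels == "object1"), n_fix_obj2 = sum(labels == "object2"),
    n_fix_env = sum(labels == "environment"), n_fix_total = length(labels),
    head_path_m = hp,
    primary_share = ratio$primary_share, secondary_share = ratio$secondary_share,
    primary_id = ratio$primary_id %||% NA_character_,
    grp_runs = prof$n_runs,
    flagged = paste(flagged, collapse = "; "),
    stringsAsFactors = FALSE
  )
  for (b in names(prof$shares)) out[[paste0("grp_share_", b)]] <- unname(prof$shares[b])
  attr(out, "grouping") <- prof
  out
}
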