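# Orchestration: simulate -> synchronize -> detect -> assign -> metrics ->
# stats as one reproducible run. All computation lives in the module
# functions; this file wires them together and writes the outputs.

#' Run configuration
#'
#' @param mode `"simulate"` (generate the experiment in memory) or `"load"`
#'   (read trial directories written by [simulate_experiment()] or conforming
#'   to the same schemas).
#' @param seed RNG seed for simulate mode.
#' @param n_subjects,n_trials design size for simulate mode.
#' @param params [behavior_params()].
#' @param detector [detector_config()].
#' @param assignment [assignment_config()].
#' @param analysis [analysis_config()].
#' @param min_step head-path noise floor, meters.
#' @param input_dir trial directory for load mode.
#' @param out_dir output directory (metrics CSV, stats JSON, report md).
#' @export
run_config <- function(mode = c("simulate", "load"), seed = 1L, n_subjects = 4L,
                       n_trials = 18L, params = behavior_params(),
                       detector = detector_config(), assignment = assignment_config(),
                       analysis = analysis_config(), min_step = 0.002,
                       input_dir = NULL, out_dir = NULL) {
  list(mode = match.arg(mode), seed = seed, n_subjects = n_subjects,
       n_trials = n_trials, params = params, detector = detector,
       assignment = assignment, analysis = analysis, min_step = min_step,
       input_dir = input_dir, out_dir = out_dir)
}

#' Analyze a single trial from raw streams
#'
#' Synchronize, detect fixations, assign targets, summarize.
#'
#' @param head,gaze stream data frames.
#' @param instances list of two `object_instance`.
#' @param record trial metadata (list with the trial JSON fields).
#' @param detector,assignment,min_step stage configurations.
#' @return list with `metrics` (one-row data frame), `fixations` (labeled),
#'   and `synced` sample count.
#' @export
analyze_trial <- function(head, gaze, instances, record,
                          detector = detector_config(),
                          assignment = assignment_config(), min_step = 0.002) {
  synced <- synchronize(head, gaze)
  fix <- detect_fixations(synced, detector)
  fix <- label_trial(fix, instances, assignment)
  metrics <- summarize_trial(record, fix, head, min_step = min_step)
  list(metrics = metrics, fixations = fix, n_synced = nrow(synced))
}

#' @keywords internal
load_trial_dir <- function(td) {
  streams <- read_streams(file.path(td, "head.csv"), file.path(td, "gaze.csv"))
  list(head = streams$head, gaze = streams$gaze,
       instances = list(read_object_json(file.path(td, "object1.json")),
                        read_object_json(file.path(td, "object2.json"))),
       record = read_trial_json(file.path(td, "trial.json")))
}

#' Statistical layer over a per-trial metrics table
#'
#' Repeated-measures ANOVAs (per-subject cell means) for the continuous
#' measures across the experimental factors plus the trial-block learning
#' factor, and the binomial mixed model for accuracy. Subjects missing a
#' factor level are dropped per effect with the count recorded in `note`.
#'
#' @param metrics per-trial metrics data frame (from [analyze_trial()] rows).
#' @param analysis an [analysis_config()].
#' @return list of effect-result data frames per dependent measure.
#' @export
run_stats <- function(metrics, analysis = analysis_config()) {
  d <- metrics
  d$n_fix_obj <- d$n_fix_obj1 + d$n_fix_obj2
  d$block <- learning_blocks(d$trial_index, block_size = analysis$block_size,
                             n_trials = analysis$n_blocks * analysis$block_size)
  factors <- c("complexity", "start_position", "orientation_diff_deg", "same", "block")
  dvs <- c("response_time_s", "n_fix_obj", "head_path_m", "primary_share")
  out <- lapply(dvs, function(dv) {
    rm_anova(d, dv, factors, "subject_id", alpha = analysis$alpha,
             on_missing = "drop_subjects")
  })
  names(out) <- dvs
  out$accuracy <- tryCatch(
    suppressWarnings(fit_accuracy_model(d, alpha = analysis$alpha, cfg = analysis)),
    error = function(e) {
      data.frame(effect = "accuracy_model", statistic = NA_real_, df_num = NA_integer_,
                 df_den = NA_integer_, p_value = NA_real_, significant = NA,
                 note = paste("not fitted:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  out
}

#' @keywords internal
stats_report_md <- function(stats) {
  lines <- c("# Run report: effects by dependent measure", "")
  for (dv in names(stats)) {
    tab <- stats[[dv]]
    lines <- c(lines, paste0("## ", dv), "",
               "| effect | statistic | df | p | significant |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(tab))) {
      df_str <- if (is.na(tab$df_den[i])) sprintf("%d", tab$df_num[i])
      else sprintf("%d, %d", tab$df_num[i], tab$df_den[i])
      lines <- c(lines, sprintf("| %s | %.4g | %s | %.4g | %s |",
                                tab$effect[i], tab$statistic[i], df_str,
                                tab$p_value[i], tab$significant[i]))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Run the full pipeline
#'
#' @param cfg a [run_config()].
#' @return list with `metrics` (per-trial table), `stats` (effect tables),
#'   `log` (per-stage counts). When `cfg$out_dir` is set, also writes
#'   `trial_metrics.csv`, `stats.json` and `report.md` there.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (cfg$mode == "simulate") {
    design <- generate_design(cfg$n_subjects, cfg$n_trials, seed = cfg$seed)
    set.seed(cfg$seed) # same trial-seed derivation as simulate_experiment()
    trial_seeds <- sample.int(.Machine$integer.max - 1L, nrow(design))
    trials <- lapply(seq_len(nrow(design)), function(i) {
      sim <- simulate_trial(as.list(design[i, ]), cfg$params, seed = trial_seeds[i])
      list(head = sim$head, gaze = sim$gaze, instances = sim$instances,
           record = sim$record, truth = sim$truth)
    })
  } else {
    if (is.null(cfg$input_dir)) stop_invalid("load mode requires input_dir")
    tds <- list.dirs(cfg$input_dir, recursive = FALSE)
    if (!length(tds)) stop_format("no trial directories under ", cfg$input_dir)
    trials <- lapply(tds, load_trial_dir)
  }
  rows <- vector("list", length(trials))
  n_fix_total <- 0L; n_synced_total <- 0L
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    res <- analyze_trial(tr$head, tr$gaze, tr$instances, tr$record,
                         cfg$detector, cfg$assignment, cfg$min_step)
    rows[[i]] <- res$metrics
    n_fix_total <- n_fix_total + nrow(res$fixations)
    n_synced_total <- n_synced_total + res$n_synced
  }
  metrics <- do.call(rbind, rows)
  stats <- run_stats(metrics, cfg$analysis)
  log <- list(n_trials = nrow(metrics), n_fixations = n_fix_total,
              n_synced_samples = n_synced_total,
              n_flagged = sum(nzchar(metrics$flagged)))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(cfg$out_dir, "trial_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(stats, function(x) { attr(x, "model") <- NULL; x }),
                         file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(stats_report_md(stats), file.path(cfg$out_dir, "report.md"))
  }
  list(metrics = metrics, stats = stats, log = log)
}
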