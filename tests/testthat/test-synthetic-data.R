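test_that("design: size, within-subject complexity balance, determinism", {
  d <- generate_design(47, 18, seed = 5)
  expect_equal(nrow(d), 846)
  tab <- table(d$subject_id, d$complexity)
  expect_true(all(tab == 6))
  expect_true(all(d$orientation_diff_deg %in% c(0, 90, 180)))
  expect_true(all(d$start_position %in% c("P_l", "P_s", "P_c")))
  expect_identical(generate_design(5, 18, seed = 9), generate_design(5, 18, seed = 9))
  expect_error(generate_design(4, 16), "divisible by 3")
})

test_that("simulated trials are reproducible and stay inside the arena", {
  rec <- demo_record("C_e", "P_c", 180, FALSE)
  s1 <- simulate_trial(rec, seed = 21)
  s2 <- simulate_trial(rec, seed = 21)
  expect_identical(s1$head, s2$head)
  expect_identical(s1$gaze, s2$gaze)
  p <- behavior_params()
  expect_true(all(s1$head$px_m >= -0.01 & s1$head$px_m <= p$arena[1] + 0.01))
  expect_true(all(s1$head$py_m >= -0.01 & s1$head$py_m <= p$arena[2] + 0.01))
  # streams at the nominal rates, timestamps strictly increasing from 0
  expect_equal(s1$head$t_s[1], 0)
  expect_equal(diff(s1$head$t_s), rep(1 / 120, nrow(s1$head) - 1), tolerance = 1e-9)
  expect_equal(diff(s1$gaze$t_s), rep(1 / 50, nrow(s1$gaze) - 1), tolerance = 1e-9)
})

test_that("ground truth is internally consistent", {
  sim <- simulate_trial(demo_record("C_h", "P_s", 0, TRUE), seed = 33)
  tf <- sim$truth$fixations
  expect_true(all(tf$t_end_s > tf$t_start_s))
  expect_true(all(tf$t_start_s[-1] > tf$t_end_s[-nrow(tf)])) # disjoint, ordered
  obj <- tf$object[tf$object > 0]
  runs <- rle(obj)$lengths
  expect_equal(as.integer(runs), sim$truth$group_sizes) # alternation by construction
  expect_gte(sim$truth$n_fix_obj1 + sim$truth$n_fix_obj2,
             behavior_params()$min_fixations)
  expect_true(sim$truth$answer %in% c("same", "different"))
  expect_equal(sim$truth$correct, sim$truth$answer == "same")
})

test_that("noiseless output is recovered exactly end to end", {
  set.seed(44)
  des <- generate_design(2, 18, seed = 44)
  for (i in sample(nrow(des), 6)) {
    sim <- simulate_trial(as.list(des[i, ]), seed = 4400 + i, noise = FALSE)
    res <- analyze_trial(sim$head, sim$gaze, sim$instances, sim$record, min_step = 0)
    tf <- sim$truth$fixations
    expect_equal(nrow(res$fixations), nrow(tf))
    expect_equal(res$fixations$label, tf$label)
    expect_equal(res$fixations$t_start_s, tf$t_start_s, tolerance = 1e-9)
    expect_equal(res$metrics$response_time_s, sim$truth$response_time_s, tolerance = 1e-9)
    expect_equal(res$metrics$head_path_m, sim$truth$head_path_m, tolerance = 1e-9)
  }
})

test_that("gaze noise model is calibrated to the target mean angular error", {
  set.seed(55)
  sc <- activegaze:::gaze_noise_scales(1.42, 0.12)
  expect_equal(sqrt(sc["offset"]^2 + sc["jitter"]^2) * sqrt(pi / 2), 1.42,
               tolerance = 1e-9, ignore_attr = TRUE)
  # Monte-Carlo over trial offsets and sample jitter, measured on perturbed rays
  base <- matrix(rep(c(1, 0, 0), 400), ncol = 3, byrow = TRUE)
  errs <- replicate(400, {
    off <- rnorm(2, 0, sc["offset"])
    D <- activegaze:::perturb_dirs(base, off[1] + rnorm(400, 0, sc["jitter"]),
                                   off[2] + rnorm(400, 0, sc["jitter"]))
    mean(angle_between_deg(D, base))
  })
  expect_equal(mean(errs), 1.42, tolerance = 0.1)
  # head position noise at the configured RMSE
  rec <- demo_record()
  s0 <- simulate_trial(rec, seed = 66, noise = FALSE)
  s1 <- simulate_trial(rec, seed = 66, noise = TRUE)
  dp <- as.matrix(s1$head[, 2:4]) - as.matrix(s0$head[, 2:4])
  expect_equal(sd(dp), 2e-4, tolerance = 0.1)
})

test_that("noisy recovery: detected counts track truth and labels agree", {
  set.seed(77)
  des <- generate_design(2, 18, seed = 77)
  agree <- numeric(0); derr <- numeric(0)
  for (i in 1:8) {
    sim <- simulate_trial(as.list(des[i, ]), seed = 7700 + i, noise = TRUE)
    res <- analyze_trial(sim$head, sim$gaze, sim$instances, sim$record)
    tf <- sim$truth$fixations
    derr <- c(derr, (nrow(res$fixations) - nrow(tf)) / nrow(tf))
    mids <- (tf$t_start_s + tf$t_end_s) / 2
    j <- findInterval(mids, res$fixations$t_start_s)
    ok <- j >= 1 & mids <= res$fixations$t_end_s[pmax(j, 1)]
    agree <- c(agree, mean(res$fixations$label[j[ok]] == tf$label[ok]))
  }
  expect_gte(mean(agree), 0.95)
  expect_lte(abs(mean(derr)), 0.10)
})

test_that("simulate_experiment writes a reproducible, loadable tree", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  des <- generate_design(2, 18, seed = 88)
  simulate_experiment(des, behavior_params(), d1, seed = 88)
  simulate_experiment(des, behavior_params(), d2, seed = 88)
  tds <- list.dirs(d1, recursive = FALSE)
  expect_length(tds, 36)
  # byte-identical re-run
  f1 <- file.path(tds[1], "gaze.csv")
  f2 <- file.path(list.dirs(d2, recursive = FALSE)[1], "gaze.csv")
  expect_identical(readLines(f1), readLines(f2))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"), simplifyVector = TRUE)
  expect_equal(nrow(man), 36)
  tr <- activegaze:::load_trial_dir(tds[1])
  expect_s3_class(tr$head, "data.frame")
  expect_equal(tr$record$subject_id, man$subject_id[1])
})

test_that("behavior parameters load from YAML overrides", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("walk_speed: 1.1",
               "accuracy: {C_e: 0.99, C_m: 0.95, C_h: 0.9}",
               "grouping_probs: [0.5, 0.2, 0.1, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01]"), f)
  p <- behavior_params_from_yaml(f)
  expect_equal(p$walk_speed, 1.1)
  expect_equal(unname(p$accuracy["C_h"]), 0.9)
  expect_equal(sum(p$grouping_probs), 1)
  expect_equal(p$gaze_hz, 50) # untouched defaults survive
  writeLines("no_such_parameter: 3", f)
  expect_error(behavior_params_from_yaml(f), "unknown behavior parameter")
})
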