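test_that("response time is the first-fixation-to-answer interval", {
  expect_equal(response_time(1.0, 5.2), 4.2)
  expect_error(response_time(5.2, 1.0), "after the first fixation")
  expect_error(response_time(NA, 1), "finite")
})

test_that("grouping profile: worked examples and bin boundaries", {
  p <- grouping_profile(c("object1", "object2", "object1", "object2"))
  expect_equal(unname(p$counts["1"]), 4L)
  expect_equal(unname(p$shares["1"]), 100)
  expect_equal(p$n_runs, 4L)

  # environment removed without splitting the run
  p2 <- grouping_profile(c("object1", "object1", "environment",
                           "object2", "object2", "object2"))
  expect_equal(unname(p2$counts[c("2", "3")]), c(1L, 1L))
  expect_equal(p2$n_runs, 2L)
  expect_equal(p2$n_object_fixations, 5L)

  # an environment glance inside a run splits only in split mode
  p3 <- grouping_profile(c("object1", "environment", "object1"))
  expect_equal(unname(p3$counts["2"]), 1L)
  p4 <- grouping_profile(c("object1", "environment", "object1"),
                         split_on_environment = TRUE)
  expect_equal(unname(p4$counts["1"]), 2L)

  p5 <- grouping_profile(c(rep("object1", 12), "object2"))
  expect_equal(unname(p5$counts[c("1", "higher")]), c(1L, 1L))

  p0 <- grouping_profile(character(0))
  expect_equal(sum(p0$counts), 0L)
  expect_equal(sum(p0$shares), 0)
})

test_that("grouping profile matches the brute-force oracle on random sequences", {
  set.seed(23)
  for (r in 1:2000) {
    labs <- sample(c("object1", "object2", "environment"), sample(0:12, 1),
                   replace = TRUE)
    p <- grouping_profile(labs)
    expect_identical(p$counts, grouping_oracle(labs))
    if (p$n_runs > 0) {
      expect_equal(sum(p$shares), 100, tolerance = 1e-9)
      expect_lte(p$n_runs, sum(labs != "environment"))
      expect_equal(sum(p$run_lengths), sum(labs != "environment"))
    }
  }
})

test_that("fixation ratio: shares, tie-break, and relabeling invariance", {
  r <- fixation_ratio(c("object1", "object1", "object1", "object2"))
  expect_equal(c(r$primary_share, r$secondary_share), c(75, 25))
  expect_equal(r$primary_id, "object1")

  tie <- fixation_ratio(c("object2", "object1"))
  expect_equal(tie$primary_share, 50)
  expect_equal(tie$primary_id, "object2") # first-fixated wins the tie

  und <- fixation_ratio(c("environment"))
  expect_true(is.na(und$primary_share))
  expect_match(und$flagged, "no object fixations")

  # exhaustive over all label sequences of length <= 6: primary share >= 50,
  # shares sum to 100, and swapping o1/o2 flips only primary_id
  for (n in 1:6) {
    grid <- expand.grid(rep(list(c("object1", "object2")), n), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      labs <- unlist(grid[i, ], use.names = FALSE)
      r1 <- fixation_ratio(labs)
      expect_gte(r1$primary_share, 50)
      expect_equal(r1$primary_share + r1$secondary_share, 100)
      swapped <- ifelse(labs == "object1", "object2", "object1")
      r2 <- fixation_ratio(swapped)
      expect_equal(r1$primary_share, r2$primary_share)
      expect_false(r1$primary_id == r2$primary_id)
    }
  }
})

test_that("normalized response time reproduces the per-complexity worked examples", {
  expect_equal(normalized_response_time(40.03, 7), 5.72)
  expect_equal(normalized_response_time(42.01, 10), 4.2)
  expect_equal(normalized_response_time(60.53, 18), 3.36)
  expect_error(normalized_response_time(10, 0), "n_blocks")
})

test_that("summarize_trial populates every field from a simulated trial", {
  rec0 <- demo_record()
  sim <- simulate_trial(rec0, seed = 404, noise = FALSE)
  res <- analyze_trial(sim$head, sim$gaze, sim$instances, sim$record, min_step = 0)
  m <- res$metrics
  expect_true(m$correct == (sim$record$answer == "same"))
  expect_equal(m$response_time_s, sim$truth$response_time_s, tolerance = 1e-9)
  expect_equal(m$n_fix_obj1, sim$truth$n_fix_obj1)
  expect_equal(m$n_fix_obj2, sim$truth$n_fix_obj2)
  expect_equal(m$n_fix_env, sim$truth$n_fix_env)
  expect_equal(m$head_path_m, sim$truth$head_path_m, tolerance = 1e-9)
  expect_equal(m$flagged, "")
  expect_gte(m$primary_share, 50)
  # grouping profile of the detected labels equals the scheduled group sizes
  prof <- attr(m, "grouping")
  oracle <- grouping_oracle(res$fixations$label)
  expect_identical(prof$counts, oracle)
  expect_equal(sort(prof$run_lengths), sort(sim$truth$group_sizes))
})

test_that("summarize_trial flags trials without usable fixations", {
  rec <- list(subject_id = "S01", trial_index = 2L, complexity = "C_e",
              start_position = "P_s", orientation_diff_deg = 0, same = FALSE,
              answer = "different", answer_time_s = 3)
  head <- data.frame(t_s = c(0, 0.5), px_m = 0, py_m = 0, pz_m = 1.6,
                     qw = 1, qx = 0, qy = 0, qz = 0)
  m <- summarize_trial(rec, empty_fixations_df(), head)
  expect_match(m$flagged, "no fixations")
  expect_true(is.na(m$response_time_s))
  expect_true(m$correct)
})
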