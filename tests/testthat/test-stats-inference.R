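# Balanced within-subject table: one value per subject x level.
make_rm_table <- function(m, k, effect = rep(0, k), sd = 1, subj_sd = 1) {
  d <- expand.grid(subject_id = sprintf("S%02d", seq_len(m)), level = seq_len(k))
  subj <- rnorm(m, 0, subj_sd)
  d$y <- subj[as.integer(factor(d$subject_id))] + effect[d$level] + rnorm(nrow(d), 0, sd)
  d$level <- factor(d$level)
  d
}

test_that("learning blocks are consecutive triples of trials", {
  expect_equal(learning_blocks(1L), 1L)
  expect_equal(learning_blocks(3L), 1L)
  expect_equal(learning_blocks(4L), 2L)
  expect_equal(learning_blocks(18L), 6L)
  expect_equal(learning_blocks(1:18), rep(1:6, each = 3))
  expect_error(learning_blocks(0L), "1..18")
  expect_error(learning_blocks(19L), "1..18")
})

test_that("repeated-measures df: 3 levels x 47 subjects -> (2, 92); 6 levels -> (5, 230)", {
  set.seed(31)
  r3 <- rm_anova(make_rm_table(47, 3), "y", "level", "subject_id")
  expect_equal(c(r3$df_num, r3$df_den), c(2, 92))
  r6 <- rm_anova(make_rm_table(47, 6), "y", "level", "subject_id")
  expect_equal(c(r6$df_num, r6$df_den), c(5, 230))
  expect_true(all(r3$p_value >= 0 & r3$p_value <= 1))
})

test_that("rm_anova F matches a from-scratch sums-of-squares oracle", {
  set.seed(32)
  for (r in 1:5) {
    m <- sample(3:8, 1); k <- sample(2:4, 1)
    d <- make_rm_table(m, k, effect = rnorm(k))
    got <- rm_anova(d, "y", "level", "subject_id")
    # manual decomposition on the m x k cell table
    Y <- matrix(d$y[order(d$subject_id, d$level)], nrow = m, byrow = TRUE)
    grand <- mean(Y)
    ss_cond <- m * sum((colMeans(Y) - grand)^2)
    ss_err <- sum((Y - outer(rowMeans(Y), rep(1, k)) -
                     outer(rep(1, m), colMeans(Y)) + grand)^2)
    f_oracle <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (m - 1)))
    expect_equal(got$statistic, f_oracle, tolerance = 1e-9)
    expect_equal(got$p_value,
                 pf(f_oracle, k - 1, (k - 1) * (m - 1), lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("rm_anova aggregates unbalanced trials to per-subject cell means first", {
  set.seed(33)
  d <- make_rm_table(10, 3)
  # duplicate some rows with jitter: cell means must drive the result
  extra <- d[sample(nrow(d), 15, replace = TRUE), ]
  extra$y <- extra$y + rnorm(15, 0, 0.1)
  both <- rbind(d, extra)
  agg <- aggregate(y ~ subject_id + level, both, mean)
  expect_equal(rm_anova(both, "y", "level", "subject_id")$statistic,
               rm_anova(agg, "y", "level", "subject_id")$statistic,
               tolerance = 1e-12)
})

test_that("rm_anova is invariant to relabeling, level permutation, and dv shift", {
  set.seed(34)
  d <- make_rm_table(12, 3, effect = c(0, 0.4, 0.8))
  f0 <- rm_anova(d, "y", "level", "subject_id")$statistic
  d2 <- d; d2$subject_id <- sprintf("Z%02d", 13 - as.integer(factor(d$subject_id)))
  expect_equal(rm_anova(d2, "y", "level", "subject_id")$statistic, f0, tolerance = 1e-12)
  d3 <- d; d3$level <- factor(c(3, 1, 2)[as.integer(d$level)])
  expect_equal(rm_anova(d3, "y", "level", "subject_id")$statistic, f0, tolerance = 1e-12)
  d4 <- d; d4$y <- d$y + 100
  expect_equal(rm_anova(d4, "y", "level", "subject_id")$statistic, f0, tolerance = 1e-9)
})

test_that("missing cells raise an explicit design error unless subjects are dropped", {
  set.seed(35)
  d <- make_rm_table(8, 3)
  d <- d[!(d$subject_id == "S03" & d$level == 2), ]
  expect_error(rm_anova(d, "y", "level", "subject_id"),
               class = "activegaze_missing_design")
  r <- rm_anova(d, "y", "level", "subject_id", on_missing = "drop_subjects")
  expect_equal(c(r$df_num, r$df_den), c(2, 2 * 6)) # 7 complete subjects
  expect_match(r$note, "dropped 1")
  dz <- make_rm_table(6, 3, sd = 0); dz$y <- 1
  expect_error(rm_anova(dz, "y", "level", "subject_id"),
               class = "activegaze_degenerate_design")
})

test_that("rm_anova type-I error is near alpha on null simulations", {
  set.seed(36)
  rej <- replicate(200, {
    r <- rm_anova(make_rm_table(20, 3), "y", "level", "subject_id")
    r$p_value < 0.05
  })
  ci <- binom.test(sum(rej), length(rej), 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("two-way interaction mode tests the cross on complete cell tables", {
  set.seed(37)
  m <- 10
  d <- expand.grid(subject_id = sprintf("S%02d", 1:m), a = factor(1:2), b = factor(1:3))
  d$y <- rnorm(nrow(d))
  r <- rm_anova(d, "y", c("a", "b"), "subject_id", interactions = TRUE)
  expect_equal(r$effect, c("a", "b", "a:b"))
  expect_equal(r$df_num, c(1, 2, 2))
  expect_equal(r$df_den, c(9, 18, 18))
})

test_that("accuracy GLMM flags complete separation and returns per-effect tests", {
  set.seed(38)
  d <- generate_design(12, 18)
  d$correct <- TRUE
  expect_warning(res <- fit_accuracy_model(d), "separation")
  expect_true(all(is.na(res$p_value)))

  re <- rnorm(12, 0, 0.5); names(re) <- sprintf("S%02d", 1:12)
  d$correct <- runif(nrow(d)) < plogis(qlogis(0.9) + re[d$subject_id])
  res <- fit_accuracy_model(d)
  expect_equal(res$effect, c("complexity", "start_position", "orientation", "same", "block"))
  expect_equal(res$df_num, c(2L, 2L, 2L, 1L, 5L))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_s4_class(attr(res, "model"), "glmerMod")
})

test_that("Greenhouse-Geisser correction deflates p without changing F", {
  set.seed(39)
  m <- 12; k <- 4
  d <- expand.grid(subject_id = sprintf("S%02d", 1:m), level = factor(1:k))
  subj <- rnorm(m)
  # non-spherical covariance: one level much noisier and correlated trend
  d$y <- subj[as.integer(factor(d$subject_id))] +
    as.integer(d$level) * subj[as.integer(factor(d$subject_id))] * 0.5 +
    rnorm(nrow(d), 0, ifelse(d$level == 1, 0.2, 1.5))
  r0 <- rm_anova(d, "y", "level", "subject_id")
  r1 <- rm_anova(d, "y", "level", "subject_id", gg_correction = TRUE)
  expect_equal(r1$statistic, r0$statistic)
  expect_gte(r1$p_value, r0$p_value) # epsilon <= 1 never sharpens the test
  expect_match(r1$note, "GG epsilon")
  eps <- as.numeric(sub(".*GG epsilon = ", "", r1$note))
  expect_true(eps >= 1 / (k - 1) && eps <= 1)
})
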