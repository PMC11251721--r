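cfg <- build_main_arena()

test_that("summarize_session computes visit percentages and aggregates", {
  p <- default_params("expert")
  s <- simulate_session(p, cfg, n_trials = 40, seed = 12)
  sm <- summarize_session(s, cfg)
  m <- session_metrics(s, cfg)
  expect_equal(sm$n_trials, 40)
  expect_equal(sm$high_visit_pct, 100 * sum(m$outcome == "high") / 40)
  expect_equal(sm$high_visit_pct + sm$low_visit_pct + sm$timeout_pct, 100)
  expect_equal(sm$mean_crossings, mean(m$n_perimeter_crossings))
  expect_equal(sm$dd_mean_vector$length,
               mean_vector(m$departing_direction[!is.na(m$departing_direction)])$length)
  # noise-free expert session: zero deviation, unit mean vector
  p0 <- default_params("expert", kappa_align = Inf, kappa_run = Inf)
  s0 <- simulate_session(p0, cfg, n_trials = 12, seed = 1)
  sm0 <- summarize_session(s0, cfg)
  expect_equal(sm0$high_visit_pct, 100)
  expect_equal(sm0$mean_dd_deviation, 0, tolerance = 1e-6)
  expect_equal(sm0$dd_mean_vector$length, 1, tolerance = 1e-10)
})

test_that("training criteria apply the phase-specific thresholds", {
  base <- list(n_trials = 60, n_completed = 60, high_visit_pct_completed = 80,
               mean_excess = 0.5, session_duration = 1500)
  class(base) <- "session_summary"
  expect_true(evaluate_criteria(base, "pre_training")$passed)
  low_visit <- base; low_visit$high_visit_pct_completed <- 74
  r <- evaluate_criteria(low_visit, "pre_training")
  expect_false(r$passed)
  expect_match(r$reasons, "visit percentage", all = FALSE)
  # boundary: exactly 75% fails the strict > 75 rule
  at75 <- base; at75$high_visit_pct_completed <- 75
  expect_false(evaluate_criteria(at75, "pre_training")$passed)
  slow <- base; slow$session_duration <- 41 * 60
  expect_false(evaluate_criteria(slow, "pre_training")$passed)
  # post-training: 40 trials, excess < 1 m
  post <- base; post$n_trials <- 40; post$mean_excess <- 0.9
  expect_true(evaluate_criteria(post, "post_training")$passed)
  # probe: strict < 0.1 m excess; exactly 0.1 fails
  probe <- base; probe$n_trials <- 40; probe$mean_excess <- 0.1
  expect_false(evaluate_criteria(probe, "probe")$passed)
  probe$mean_excess <- 0.099
  expect_true(evaluate_criteria(probe, "probe")$passed)
  expect_error(evaluate_criteria(base, "warmup"), "arg")
})

test_that("find_pre_post applies the two-consecutive-days rule", {
  pp <- find_pre_post(c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(pp$pre, c(2L, 3L))
  expect_equal(pp$post, c(4L, 5L))
  expect_error(find_pre_post(c(TRUE, TRUE, TRUE)), "before day 3")
  expect_error(find_pre_post(c(FALSE, TRUE, FALSE, TRUE, FALSE)),
               "no pair of consecutive")
  # isolated pass before the true pair is skipped
  pp2 <- find_pre_post(c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(pp2$post, c(5L, 6L))
})

test_that("novice-to-expert day series shows the learning effect", {
  # 4 novice days then 2 expert days emulate acquisition
  days <- c(rep("novice", 4), rep("expert", 2))
  summaries <- lapply(seq_along(days), function(i) {
    s <- simulate_session(default_params(days[i]), cfg, n_trials = 60,
                          seed = 700 + i, day = i)
    summarize_session(s, cfg)
  })
  pp <- find_pre_post(summaries, phase = "pre_training")
  expect_equal(pp$post, c(5L, 6L))
  pre_dev <- mean(vapply(pp$pre, function(i)
    summaries[[i]]$mean_dd_deviation, numeric(1)))
  post_dev <- mean(vapply(pp$post, function(i)
    summaries[[i]]$mean_dd_deviation, numeric(1)))
  expect_lt(post_dev, pre_dev)
})

test_that("merge_pbs gates on the paired Wilcoxon test", {
  subj <- sprintf("s%d", 1:8)
  d <- fake_summary_df(subj, "dPBS", visit = c(90, 92, 88, 95, 91, 89, 93, 94),
                       crossings = c(1, 3, 1.2, 1.4, 1.1, 1.6, 1.3, 1.2),
                       speed = 15 + (1:8) / 10)
  i <- d; i$condition <- "iPBS"
  # identical sessions merge unchanged
  r <- merge_pbs(d, i, metrics = c("high_visit_pct", "mean_crossings"))
  expect_true(all(r$gate$merged))
  expect_equal(r$merged$high_visit_pct, d$high_visit_pct)
  # per-subject averaging: (1 crossing, 3 crossings) -> 2
  i2 <- d; i2$mean_crossings <- c(3, 1, 1.2, 1.4, 1.1, 1.6, 1.3, 1.2)
  r2 <- merge_pbs(d, i2, metrics = "mean_crossings")
  expect_equal(r2$merged$mean_crossings[1:2], c(2, 2))
  # strongly differing sessions: merge refused for that metric only
  i3 <- d; i3$mean_crossings <- d$mean_crossings + 2
  r3 <- merge_pbs(d, i3, metrics = c("high_visit_pct", "mean_crossings"))
  g <- r3$gate
  expect_false(g$merged[g$metric == "mean_crossings"])
  expect_true(g$merged[g$metric == "high_visit_pct"])
  expect_true(all(is.na(r3$merged$mean_crossings)))
  # idempotence on already-merged input
  r4 <- merge_pbs(r$merged, r$merged, metrics = "high_visit_pct")
  expect_equal(r4$merged$high_visit_pct, r$merged$high_visit_pct)
  # unpaired subjects rejected
  d2 <- d; d2$subject_id[1] <- "zz"
  expect_error(merge_pbs(d2, i, metrics = "high_visit_pct"), "paired")
})

test_that("compare_conditions runs the scalar and angular workflow", {
  subj <- sprintf("s%d", 1:6)
  set.seed(44)
  mk <- function(cond, shift) fake_summary_df(
    subj, cond, visit = 90 + rnorm(6) + shift,
    crossings = 1 + abs(rnorm(6, 0.2)), speed = 15 + rnorm(6))
  summaries <- rbind(mk("PBS", 0), mk("dMUS", -2), mk("iMUS", -10))
  # dMUS/iMUS both dispersed so their pairwise average mean vector length
  # falls below the 0.45 gate
  angles <- list(dd = list(PBS = rvonmises(100, 180, 8),
                           dMUS = rvonmises(100, 160, 1.2),
                           iMUS = rvonmises(100, 140, 0.2)))
  res <- compare_conditions(summaries,
                            scalar_metrics = c("high_visit_pct", "mean_speed"),
                            angles = angles, n_perm = 200, seed = 2)
  expect_equal(nrow(res$scalar_table), 2)
  expect_equal(res$scalar$high_visit_pct$df, c(2, 10))
  expect_equal(nrow(res$posthoc_table), 6)  # 3 pairs x 2 metrics
  ww_tab <- subset(res$angular_table, test == "watson_williams")
  expect_equal(nrow(ww_tab), 4)             # omnibus + 3 pairs
  # the dMUS vs iMUS pair is too dispersed: its gate closes
  di <- subset(ww_tab, contrast == "dMUS vs iMUS")
  expect_false(di$applicable)
  # identical conditions: p = 1 everywhere, no post hoc significant
  same <- rbind(mk("A", 0), mk("B", 0), mk("C", 0))
  same$high_visit_pct <- rep(same$high_visit_pct[1:6], 3)
  same$mean_speed <- rep(same$mean_speed[1:6], 3)
  res0 <- compare_conditions(same, scalar_metrics = c("high_visit_pct", "mean_speed"))
  expect_true(all(res0$scalar_table$p_value == 1))
  expect_true(all(res0$posthoc_table$p_bonferroni == 1))
  expect_error(compare_conditions(summaries[summaries$condition == "PBS", ]),
               ">= 2 conditions")
  # mismatched subjects
  bad <- summaries[-1, ]
  expect_error(compare_conditions(bad, scalar_metrics = "high_visit_pct"),
               "mismatched subjects")
})
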