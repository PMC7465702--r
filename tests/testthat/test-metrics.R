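# metrics module: completion rate, semi-asynchronous accuracy, ITR,
# sequential expected accuracy, t-ratio arithmetic, and aggregation against
# the bundled reference tables.

fake_log <- function(step_outcomes, events = NULL) {
  structure(list(
    events = events %||% data.frame(time = numeric(0), step = character(0),
                                    role = character(0),
                                    predicted = character(0),
                                    truth = character(0),
                                    outcome = character(0)),
    step_outcomes = step_outcomes, trial_id = "T001",
    learning = "before"), class = "trial_log")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("completion rate interpolates linearly between the anchors", {
  cfg <- fsm_config()
  so <- data.frame(step = c("OPEN", "GRAB", "HOLD"),
                   triggered_by = c("bci", "timeout", "auto"),
                   latency = c(2, 6, 6), hold_successes = c(NA, NA, 4L))
  log <- fake_log(so)
  expect_equal(completion_rate(log, "OPEN", cfg), (6 - 2) / 6 * 100)
  expect_equal(completion_rate(log, "GRAB", cfg), 0)
  expect_equal(completion_rate(log, "HOLD", cfg), 4 / 6 * 100)
  so0 <- data.frame(step = "OPEN", triggered_by = "bci", latency = 0,
                    hold_successes = NA)
  expect_equal(completion_rate(fake_log(so0), "OPEN", cfg), 100)
  expect_error(completion_rate(log, "FLY", cfg), "unknown step")
})

test_that("semi-asynchronous accuracy excludes delays and pools by FES", {
  ev <- data.frame(
    time = 1:15,
    step = c(rep("OPEN", 12), rep("STOP_FES", 3)),
    role = c(rep("ACT", 10), "SMR", "SMR", rep("FES", 3)),
    predicted = "x", truth = "x",
    outcome = c(rep("correct", 7), rep("error", 3), "delay", "delay",
                "correct", "correct", "error"),
    stringsAsFactors = FALSE)
  # pad delays: spec example has 5 SMR delays, 7 correct + 3 error ACT
  ev <- rbind(ev, data.frame(time = 16:18, step = "OPEN", role = "SMR",
                             predicted = "x", truth = "x",
                             outcome = "delay"))
  acc <- semi_async_accuracy(fake_log(NULL, events = ev))
  expect_equal(acc[["No-FES"]], 70)
  expect_equal(acc[["Yes-FES"]], 2 / 3 * 100)
  # include_delays flag changes the denominator
  acc2 <- semi_async_accuracy(fake_log(NULL, events = ev),
                              include_delays = TRUE)
  expect_equal(acc2[["No-FES"]], 7 / 15 * 100)

  all_ok <- ev
  all_ok$outcome <- "correct"
  expect_equal(unname(semi_async_accuracy(fake_log(NULL, events = all_ok))),
               c(100, 100, 100))
})

test_that("ITR follows the Wolpaw formula", {
  expect_equal(itr(1, 2, 10), 10)
  expect_equal(itr(0.5, 2, 10), 0)
  expect_equal(itr(0.875, 2, 12), 5.48, tolerance = 0.001)
  expect_error(itr(0.8, 1), "N must be")
  # monotone increasing in P on [1/N, 1]
  ps <- seq(0.5, 1, by = 0.05)
  vals <- vapply(ps, itr, numeric(1), N = 2, decisions_per_min = 10)
  expect_true(all(diff(vals) > -1e-12))
  expect_true(all(vals >= -1e-12))
})

test_that("sequential expected accuracy reproduces the worked arithmetic", {
  r <- sequential_expected_accuracy(c(0.7, 0.7))
  expect_equal(unname(r), c(0.49, 0.30, 0.21))
  expect_equal(sum(r), 1, tolerance = 1e-12)

  r2 <- sequential_expected_accuracy(c(0.7349, 0.7125))
  expect_equal(round(r2[["p_correct"]] * 100, 1), 52.4)

  expect_equal(unname(sequential_expected_accuracy(c(1, 1))), c(1, 0, 0))
  expect_error(sequential_expected_accuracy(numeric(0)), "empty")
  # sums to 1 over random stage accuracies
  withr::with_seed(60, for (i in 1:20) {
    expect_equal(sum(sequential_expected_accuracy(runif(2))), 1,
                 tolerance = 1e-12)
  })
})

test_that("two-stage Monte-Carlo matches (0.49, 0.30, 0.21)", {
  n <- 1e5
  withr::with_seed(61, {
    detect <- runif(n) < 0.7
    correct <- detect & (runif(n) < 0.7)
  })
  p_hat <- c(mean(correct), mean(!detect), mean(detect & !correct))
  expect_equal(p_hat, c(0.49, 0.30, 0.21), tolerance = 0.01)
})

test_that("t-ratio arithmetic matches the workload table", {
  tab <- reference_tables("workload_ttest")
  t_ratios <- t_from_summary(tab$estimate, tab$standard_error)
  expect_equal(round(t_ratios[tab$question == "Mental Demand"], 2), 2.41)
  expect_equal(round(t_ratios[tab$question == "Performance"], 2), -2.86)
  expect_equal(round(t_ratios[tab$question == "Frustration"], 2), 3.8)
  expect_equal(t_from_summary(0, 2), 0)
  expect_equal(p_two_tailed(0, 7), 1)
  # printed significance at df = 7
  expect_lt(p_two_tailed(2.41, 7), 0.05)
  expect_error(t_from_summary(1, 0), "positive")
})

test_that("aggregate_summary reproduces printed averages", {
  t5 <- reference_tables("accuracy_by_iv")
  agg <- aggregate_summary(t5)
  avg <- agg[agg$subject == "Average", ]
  expect_equal(round(avg$after_no_fes, 1), 61.9)

  t6 <- reference_tables("itr_by_iv")
  agg6 <- aggregate_summary(t6)
  expect_equal(round(agg6$grand[agg6$subject == "Average"], 2), 12.30)

  one <- aggregate_summary(data.frame(subject = "S01", v = 5))
  expect_equal(one$v[one$subject == "Average"], 5)
  expect_true(is.na(one$v[one$subject == "SD"]))
})

test_that("session_metrics summarizes a virtual session", {
  subj <- virtual_subject(0.9, 0.9, 0.9)
  logs <- run_session(subj, fsm_config(n_trials = 6), seed = 8,
                      start_after = 3)
  m <- session_metrics(logs, fsm_config(n_trials = 6))
  expect_setequal(unique(m$condition), c("No-FES", "Yes-FES"))
  expect_true(all(m$completion_rate >= 0 & m$completion_rate <= 100))
  expect_true(all(is.na(m$accuracy) | (m$accuracy >= 0 & m$accuracy <= 100)))
})
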