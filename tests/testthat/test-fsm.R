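# online_fsm module: transition rules, timeouts, sequence integrity,
# liveness, and the adaptation partition of a session.

test_that("fsm_step applies the documented transition rules", {
  cfg <- fsm_config()
  st <- fsm_init(cfg)
  expect_equal(st$role, "SMR")

  # window 1: no detection -> delay
  st <- fsm_step(st, list(time = 0, role = "SMR", predicted = "NONE",
                          truth = "DETECT"), cfg)
  expect_equal(st$events[[1]]$outcome, "delay")
  expect_equal(st$windows_used, 1L)

  # window 2 (t = 1 s): detection -> same-window ACT, then FCO match
  st <- fsm_step(st, list(time = 1, role = "SMR", predicted = "DETECT",
                          truth = "DETECT"), cfg)
  expect_equal(st$role, "ACT")
  expect_equal(st$windows_used, 1L) # same window, not consumed yet
  st <- fsm_step(st, list(time = 1, role = "ACT", predicted = "FCO",
                          truth = "FCO"), cfg)
  so <- st$step_outcomes[[1]]
  expect_equal(so$step, "OPEN")
  expect_equal(so$triggered_by, "bci")
  expect_equal(so$latency, 1) # detected at t = 1 s
  expect_equal(st$role, "FES") # now at STOP_FES
  expect_true(st$fes_active)

  # ACT mismatch reverts to SMR
  st2 <- fsm_init(cfg)
  st2 <- fsm_step(st2, list(time = 0, role = "SMR", predicted = "DETECT",
                            truth = "DETECT"), cfg)
  st2 <- fsm_step(st2, list(time = 0, role = "ACT", predicted = "SOG",
                            truth = "FCO"), cfg)
  expect_equal(st2$role, "SMR")
  expect_equal(st2$events[[2]]$outcome, "error")

  # role mismatch is rejected
  expect_error(fsm_step(st2, list(time = 1, role = "FES",
                                  predicted = "STOP", truth = "STOP"), cfg),
               "inconsistent")
})

test_that("timeouts auto-trigger after the maximum analysis time", {
  cfg <- fsm_config()
  st <- fsm_init(cfg)
  for (i in 1:6)
    st <- fsm_step(st, list(time = i - 1, role = "SMR", predicted = "NONE",
                            truth = "DETECT"), cfg)
  so <- st$step_outcomes[[1]]
  expect_equal(so$step, "OPEN")
  expect_equal(so$triggered_by, "timeout")
  expect_equal(so$latency, 6)
})

test_that("all-perfect and all-failing subjects produce the two extremes", {
  cfg <- fsm_config()
  perfect <- run_trial(virtual_subject(1, 1, 1), cfg, seed = 1)
  expect_true(all(perfect$step_outcomes$triggered_by[
    perfect$step_outcomes$step %in% c("OPEN", "STOP_FES", "GRAB")] ==
      "bci"))
  expect_true(all(perfect$step_outcomes$latency[
    perfect$step_outcomes$triggered_by == "bci"] == 0))
  expect_false(any(perfect$events$outcome == "error"))
  expect_equal(perfect$step_outcomes$hold_successes[
    perfect$step_outcomes$step == "HOLD"], 6)

  never <- run_trial(virtual_subject(0, 0, 0), cfg, seed = 1)
  bci_steps <- never$step_outcomes$step %in% c("OPEN", "STOP_FES", "GRAB")
  expect_true(all(never$step_outcomes$triggered_by[bci_steps] == "timeout"))
  expect_equal(never$step_outcomes$hold_successes[
    never$step_outcomes$step == "HOLD"], 0)
})

test_that("step order, break placement, and latency bounds always hold", {
  cfg <- fsm_config()
  expected_steps <- c("OPEN", "STOP_FES", "MOVE", "GRAB", "MOVE_BALL",
                      "HOLD")
  random_source <- function(role, truth) {
    pos <- smrfes:::role_positive[[role]]
    neg <- smrfes:::role_negative[[role]]
    sample(c(pos, neg), 1)
  }
  for (k in 1:25) {
    log <- run_trial(random_source, cfg, seed = k)
    expect_equal(log$step_outcomes$step, expected_steps)
    expect_true(all(log$step_outcomes$latency <= cfg$max_analysis_time,
                    na.rm = TRUE))
    hs <- log$step_outcomes$hold_successes
    expect_true(all(hs[!is.na(hs)] <= 6))
    # events are time-ordered
    expect_true(!is.unsorted(log$events$time))
    # the break follows STOP_FES: first GRAB-step event starts >= 10 s
    # after the last STOP_FES event
    ev <- log$events
    t_stop <- max(ev$time[ev$step == "STOP_FES"])
    t_grab <- min(ev$time[ev$step == "GRAB"])
    expect_gte(t_grab - t_stop, cfg$break_duration)
  }
})

test_that("every random-decision trial terminates (liveness)", {
  cfg <- fsm_config()
  random_source <- function(role, truth) {
    pos <- smrfes:::role_positive[[role]]
    neg <- smrfes:::role_negative[[role]]
    sample(c(pos, neg), 1)
  }
  n_done <- 0
  for (k in seq_len(1000)) {
    log <- run_trial(random_source, cfg, seed = 100000 + k)
    n_done <- n_done + (nrow(log$step_outcomes) == 6)
  }
  expect_equal(n_done, 1000)
})

test_that("timeout frequency matches the two-stage Bernoulli oracle", {
  # per window: detect w.p. 0.5, then correct ACT w.p. 0.5 -> success 0.25;
  # timeout after 6 windows w.p. 0.75^6
  subj <- virtual_subject(0.5, 0.5, 0.5)
  n <- 200
  timeouts <- withr::with_seed(7, vapply(seq_len(n), function(i) {
    log <- run_trial(subj, fsm_config(), seed = sample.int(1e6, 1))
    log$step_outcomes$triggered_by[log$step_outcomes$step == "OPEN"] ==
      "timeout"
  }, logical(1)))
  p <- 0.75^6
  band <- stats::qbinom(c(0.025, 0.975), n, p) / n
  expect_gte(mean(timeouts), band[1])
  expect_lte(mean(timeouts), band[2])
})

test_that("run_session partitions trials around the adaptation onset", {
  subj <- virtual_subject(0.8, 0.8, 0.8)
  logs <- run_session(subj, fsm_config(n_trials = 20), seed = 3)
  learning <- vapply(logs, function(l) l$learning, character(1))
  expect_equal(sum(learning == "before"), 10)
  expect_equal(sum(learning == "after"), 10)

  # adaptation disabled: identical decisions with and without the flag
  l1 <- run_session(subj, fsm_config(n_trials = 4), seed = 5,
                    adapt = FALSE)
  l2 <- run_session(subj, fsm_config(n_trials = 4), seed = 5,
                    adapt = FALSE)
  expect_identical(lapply(l1, function(l) l$events),
                   lapply(l2, function(l) l$events))
})

test_that("adaptation recovers accuracy under subject drift", {
  # drift of ~ a quarter class-separation per trial: strong non-stationarity
  # that visibly degrades the uncompensated second half of a session
  wins <- vapply(1:50, function(k) {
    subj <- virtual_subject(0.85, 0.85, 0.85, drift_magnitude = 0.5)
    la <- run_session(subj, fsm_config(n_trials = 20), seed = 2000 + k,
                      adapt = TRUE)
    post <- semi_async_accuracy(la[11:20])[["overall"]]
    pre <- semi_async_accuracy(la[1:10])[["overall"]]
    post >= pre
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
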