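# Semi-asynchronous fixed-sequence control loop. The task sequence is
# predetermined (open hand -> stop FES -> move -> grab ball -> move ball ->
# hold); the user self-paces each BCI-gated step through SMR detection,
# with a 6-s maximum analysis time after which the system auto-triggers,
# 5-s FES activations, and a 10-s break after stopping FES.

#' Configuration of the semi-asynchronous control loop
#'
#' @param max_analysis_time Seconds before a BCI step auto-triggers.
#' @param fes_duration Seconds of FES activation per trigger.
#' @param break_duration Seconds of rest after the stop-FES step (the BCI
#'   stops classifying during the break).
#' @param decision_interval Seconds between decision windows.
#' @param move_window Seconds allotted to the non-BCI movement steps.
#' @param n_trials Trials per session.
#' @param hold_required Correct keep-decisions for a 100 % hold (default
#'   `max_analysis_time / decision_interval` = 6).
#' @return An `fsm_config` object with the step `sequence`.
#' @export
fsm_config <- function(max_analysis_time = 6, fes_duration = 5,
                       break_duration = 10, decision_interval = 1,
                       move_window = 5, n_trials = 20,
                       hold_required = NULL) {
  if (any(c(max_analysis_time, fes_duration, break_duration,
            decision_interval, move_window) <= 0))
    stop("fsm_config: durations must be positive")
  if (max_analysis_time %% decision_interval != 0)
    stop("fsm_config: max_analysis_time must be a multiple of the decision interval")
  hold_required <- hold_required %||%
    as.integer(max_analysis_time / decision_interval)
  structure(list(
    max_analysis_time = max_analysis_time,
    fes_duration = fes_duration,
    break_duration = break_duration,
    decision_interval = decision_interval,
    move_window = move_window,
    n_trials = n_trials,
    hold_required = hold_required,
    sequence = list(
      list(id = "OPEN", type = "trigger", act_target = "FCO"),
      list(id = "STOP_FES", type = "fes", target = "STOP",
           break_after = TRUE),
      list(id = "MOVE", type = "manual"),
      list(id = "GRAB", type = "trigger", act_target = "SOG"),
      list(id = "MOVE_BALL", type = "manual"),
      list(id = "HOLD", type = "hold", target = "KEEP")
    )
  ), class = "fsm_config")
}

#' Initialize control-loop state
#'
#' @param config An [fsm_config()].
#' @param trial_id Identifier stored in the resulting log.
#' @return An `fsm_state` positioned at the first BCI step.
#' @export
fsm_init <- function(config = fsm_config(), trial_id = "T001") {
  state <- structure(list(
    step_index = 1L, role = "SMR", windows_used = 0L, time = 0,
    fes_active = FALSE, done = FALSE, trial_id = trial_id,
    events = list(), step_outcomes = list()
  ), class = "fsm_state")
  skip_non_bci(state, config)
}

step_role <- function(step) {
  switch(step$type, trigger = "SMR", fes = "FES", hold = "FES",
         stop("no role for step type ", step$type))
}

step_truth <- function(state, config) {
  step <- config$sequence[[state$step_index]]
  if (state$role == "SMR") "DETECT"
  else if (state$role == "ACT") step$act_target
  else step$target
}

# Advance over manual steps and the post-stop break; mark completion.
skip_non_bci <- function(state, config) {
  repeat {
    if (state$step_index > length(config$sequence)) {
      state$done <- TRUE
      return(state)
    }
    step <- config$sequence[[state$step_index]]
    if (step$type != "manual") {
      state$role <- step_role(step)
      state$windows_used <- 0L
      return(state)
    }
    state$step_outcomes[[length(state$step_outcomes) + 1]] <-
      list(step = step$id, triggered_by = "manual", latency = NA_real_,
           hold_successes = NA_integer_)
    state$time <- state$time + config$move_window
    state$step_index <- state$step_index + 1L
  }
}

record_event <- function(state, decision, outcome, step_id) {
  state$events[[length(state$events) + 1]] <- data.frame(
    time = decision$time, step = step_id, role = decision$role,
    predicted = decision$predicted, truth = decision$truth,
    outcome = outcome, stringsAsFactors = FALSE)
  state
}

complete_step <- function(state, config, triggered_by, latency,
                          hold_successes = NA_integer_) {
  step <- config$sequence[[state$step_index]]
  state$step_outcomes[[length(state$step_outcomes) + 1]] <-
    list(step = step$id, triggered_by = triggered_by, latency = latency,
         hold_successes = hold_successes)
  if (step$type %in% c("trigger")) state$fes_active <- TRUE
  if (step$type %in% c("fes", "hold")) state$fes_active <- FALSE
  if (isTRUE(step$break_after)) state$time <- state$time +
    config$break_duration
  state$step_index <- state$step_index + 1L
  skip_non_bci(state, config)
}

#' Advance the control loop by one decision
#'
#' Applies the transition rules: an SMR detection switches the role to ACT
#' for the same window's features; an ACT target match activates FES and
#' records the step latency; an ACT mismatch reverts to SMR; a missed SMR
#' is a delay; exhausting the maximum analysis time auto-triggers the step;
#' a correct stop-decision ends stimulation (followed by the break); each
#' correct keep-decision during the hold step increments `hold_successes`.
#'
#' @param state An `fsm_state` from [fsm_init()].
#' @param decision List with `time`, `role`, `predicted`, `truth`; `role`
#'   must match the state's current role.
#' @param config The [fsm_config()].
#' @return The updated `fsm_state`.
#' @export
fsm_step <- function(state, decision, config = fsm_config()) {
  if (state$done) stop("fsm_step: trial already complete")
  if (!identical(decision$role, state$role))
    stop(sprintf("fsm_step: decision role %s inconsistent with state role %s",
                 decision$role, state$role))
  step <- config$sequence[[state$step_index]]
  max_windows <- as.integer(config$max_analysis_time /
                              config$decision_interval)
  lat <- function() state$windows_used * config$decision_interval

  if (step$type == "trigger") {
    if (state$role == "SMR") {
      if (decision$predicted == "DETECT") {
        state <- record_event(state, decision, "correct", step$id)
        state$role <- "ACT" # same window, role switches
        return(state)
      }
      state <- record_event(state, decision, "delay", step$id)
    } else { # ACT on the same window's features
      ok <- decision$predicted == step$act_target
      state <- record_event(state, decision, if (ok) "correct" else "error",
                            step$id)
      if (ok) {
        state <- complete_step(state, config, "bci", lat())
        state$time <- state$time + config$decision_interval
        return(state)
      }
      state$role <- "SMR" # revert
    }
  } else { # fes / hold steps: keep-vs-stop decisions
    ok <- decision$predicted == step$target
    state <- record_event(state, decision, if (ok) "correct" else "error",
                          step$id)
    if (step$type == "fes" && ok) {
      state <- complete_step(state, config, "bci", lat())
      state$time <- state$time + config$decision_interval
      return(state)
    }
    if (step$type == "hold") {
      state$hold_successes <- (state$hold_successes %||% 0L) + as.integer(ok)
    }
  }
  state$windows_used <- state$windows_used + 1L
  state$time <- state$time + config$decision_interval
  if (state$windows_used >= max_windows) {
    hs <- if (step$type == "hold") (state$hold_successes %||% 0L)
          else NA_integer_
    state$hold_successes <- NULL
    trig <- if (step$type == "hold") "auto" else "timeout"
    state <- complete_step(state, config, trig, config$max_analysis_time, hs)
  }
  state
}

finalize_log <- function(state, learning = NA_character_) {
  ev <- if (length(state$events)) do.call(rbind, state$events) else
    data.frame(time = numeric(0), step = character(0), role = character(0),
               predicted = character(0), truth = character(0),
               outcome = character(0))
  so <- do.call(rbind, lapply(state$step_outcomes, function(s)
    data.frame(step = s$step, triggered_by = s$triggered_by,
               latency = s$latency, hold_successes = s$hold_successes,
               stringsAsFactors = FALSE)))
  structure(list(events = ev, step_outcomes = so, trial_id = state$trial_id,
                 learning = learning),
            class = "trial_log")
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("<trial_log %s: %d events, steps %s>\n", x$trial_id,
              nrow(x$events),
              paste(x$step_outcomes$triggered_by, collapse = "/")))
  invisible(x)
}

# Drift-free calibration: run a few trials with drift zeroed and return
# the per-role mean decision feature. This reproduces the role-specific
# stream composition (e.g. the keep-heavy FES stream) that a training set
# would exhibit.
calibrate_reference <- function(subject, config, seeds) {
  sub0 <- subject
  sub0$drift_magnitude <- 0
  feats <- list(SMR = numeric(0), ACT = numeric(0), FES = numeric(0))
  env <- environment()
  for (k in seq_along(seeds)) {
    run_trial(sub0, config, seed = seeds[k], trial_index = 1,
              on_feature = function(role, feature) {
                env$feats[[role]] <- c(env$feats[[role]], feature)
              })
  }
  lapply(feats, function(v) if (length(v)) mean(v) else 0)
}

# Build a decider function(role, truth) -> predicted from a source.
make_decider <- function(source, trial_index = 1, biases = NULL) {
  if (is.function(source)) return(source)
  if (!inherits(source, "virtual_subject"))
    stop("run_trial: source must be a virtual_subject or function")
  drift <- source$drift_magnitude * (trial_index - 1)
  get_biases <- if (is.function(biases)) biases
                else function() biases
  function(role, truth) {
    b <- if (is.null(biases)) 0 else get_biases()[[role]]
    pos <- role_positive[[role]]
    s <- if (truth == pos) 1 else -1
    x <- subject_feature(source, role, s, drift)
    list(predicted = if (x - b > 0) pos else role_negative[[role]],
         feature = x)
  }
}

#' Run one semi-asynchronous trial
#'
#' Executes the fixed sequence OPEN -> STOP_FES -> (move) -> GRAB ->
#' (move ball) -> HOLD, drawing one decision per window from `source`
#' (a [virtual_subject()] or a `function(role, truth)` returning a
#' predicted label or `list(predicted=, feature=)`).
#'
#' @param source Decision source.
#' @param config An [fsm_config()].
#' @param seed Seed for the subject's stochastic decisions.
#' @param trial_index 1-based position in the session (drift accrual).
#' @param trial_id Identifier.
#' @param on_feature Optional callback `function(role, feature)` invoked for
#'   each decision feature (used for pooled-mean adaptation).
#' @param biases Optional named list of per-role decision biases, or a
#'   zero-argument function returning one (re-read every window, so
#'   adaptation updates take effect within the trial).
#' @return A `trial_log` with time-ordered `events` and `step_outcomes`.
#' @export
run_trial <- function(source, config = fsm_config(), seed = 1,
                      trial_index = 1, trial_id = "T001",
                      on_feature = NULL, biases = NULL) {
  withr::with_seed(seed, {
    decider <- make_decider(source, trial_index, biases)
    state <- fsm_init(config, trial_id)
    guard <- 0
    while (!state$done) {
      truth <- step_truth(state, config)
      res <- decider(state$role, truth)
      if (!is.list(res)) res <- list(predicted = res, feature = NA_real_)
      if (!is.null(on_feature) && is.finite(res$feature))
        on_feature(state$role, res$feature)
      decision <- list(time = state$time, role = state$role,
                       predicted = res$predicted, truth = truth)
      state <- fsm_step(state, decision, config)
      guard <- guard + 1
      if (guard > 1000)
        stop("run_trial: no progress after 1000 decisions") # liveness guard
    }
    finalize_log(state)
  })
}

#' Run a full semi-asynchronous session with optional adaptation
#'
#' Trials 1..`start_after` use the static decision biases; from trial
#' `start_after + 1` pooled-mean adaptation tracks the per-role feature
#' stream (one update per decision window) and recenters the decision
#' threshold, compensating feature drift.
#'
#' @param subject A [virtual_subject()].
#' @param config An [fsm_config()].
#' @param seed Session seed (per-trial seeds are derived from it).
#' @param adapt Enable pooled-mean adaptation.
#' @param eta Pooled-mean updating coefficient.
#' @param start_after Static trials before adaptation starts.
#' @return List of `trial_log`s; each carries `learning` = "before"/"after".
#' @export
run_session <- function(subject, config = fsm_config(), seed = 1,
                        adapt = TRUE, eta = 0.1, start_after = 10) {
  if (config$n_trials < 1) stop("run_session: n_trials must be >= 1")
  trial_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max %/% 2, config$n_trials + 5))
  # Per-role reference feature means come from a short drift-free
  # calibration run: the analogue of the cue-based training phase that
  # precedes the online session (the subject's drift is defined relative
  # to training). Once adaptation starts, the pooled mean tracks the raw
  # online stream and the decision threshold follows its excursion from
  # that reference.
  mu0 <- calibrate_reference(subject, config,
                             seeds = trial_seeds[config$n_trials + 1:5])
  states <- list(SMR = pmean_state(mu0$SMR, eta),
                 ACT = pmean_state(mu0$ACT, eta),
                 FES = pmean_state(mu0$FES, eta))
  biases <- list(SMR = 0, ACT = 0, FES = 0)
  env <- environment()
  logs <- vector("list", config$n_trials)
  for (i in seq_len(config$n_trials)) {
    adapting <- adapt && adaptation_schedule(i, start_after)
    cb <- if (adapting) {
      function(role, feature) {
        upd <- pmean_update(env$states[[role]], feature)
        env$states[[role]] <- upd$state
        env$biases[[role]] <- upd$state$mu - mu0[[role]]
      }
    } else NULL
    logs[[i]] <- run_trial(subject, config, seed = trial_seeds[i],
                           trial_index = i,
                           trial_id = sprintf("T%03d", i),
                           on_feature = cb,
                           biases = function() env$biases)
    logs[[i]]$learning <- if (adaptation_schedule(i, start_after)) "after"
                          else "before"
  }
  logs
}

#' Write trial logs as JSON lines
#'
#' One decision event per line (trial, time, step, role, predicted, truth,
#' outcome).
#'
#' @param logs List of `trial_log`s.
#' @param path Output file.
#' @export
write_trial_logs <- function(logs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (log in logs) {
    ev <- log$events
    if (nrow(ev) == 0) next
    for (r in seq_len(nrow(ev))) {
      rec <- c(list(trial = log$trial_id, learning = log$learning),
               as.list(ev[r, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read trial logs from JSON lines
#' @param path File written by [write_trial_logs()].
#' @return List of `trial_log`s (events only; step outcomes are not
#'   serialized).
#' @export
read_trial_logs <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
  df <- do.call(rbind, lapply(recs, as.data.frame,
                              stringsAsFactors = FALSE))
  split_df <- split(df, df$trial)
  lapply(split_df, function(d) {
    structure(list(events = d[order(d$time),
                              c("time", "step", "role", "predicted",
                                "truth", "outcome")],
                   step_outcomes = NULL, trial_id = d$trial[1],
                   learning = d$learning[1]),
              class = "trial_log")
  })
}
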