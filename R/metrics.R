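# Performance reporting: completion rate, semi-asynchronous accuracy,
# information transfer rate, sequential expected accuracy, t-ratio
# arithmetic, and summary-table aggregation.

#' Completion rate of one step in a trial
#'
#' Trigger-type steps (open, grab, stop) score `(T_max - delay) / T_max *
#' 100`, where `delay` is the decision latency before success (100 % at the
#' first decision, 0 % on timeout). The hold step scores the fraction of
#' correct keep-decisions out of the maximum number of decisions.
#'
#' @param log A `trial_log`.
#' @param step Step id (`"OPEN"`, `"STOP_FES"`, `"GRAB"`, `"HOLD"`).
#' @param config The [fsm_config()] used to produce the log.
#' @return Completion rate in percent.
#' @export
completion_rate <- function(log, step, config = fsm_config()) {
  so <- log$step_outcomes
  row <- so[so$step == step, ]
  if (nrow(row) != 1) stop("completion_rate: unknown step ", step)
  tmax <- config$max_analysis_time
  if (step == "HOLD") {
    maxdec <- tmax / config$decision_interval
    return(row$hold_successes / maxdec * 100)
  }
  if (row$triggered_by == "timeout") return(0)
  (tmax - row$latency) / tmax * 100
}

#' Semi-asynchronous accuracy per FES condition
#'
#' Accuracy = correct / (correct + error); missed SMR detections are delays,
#' not errors, and are excluded from the denominator (set
#' `include_delays = TRUE` for the alternative convention). Events from the
#' open and grab steps pool into the No-FES condition, stop and hold into
#' Yes-FES.
#'
#' @param logs List of `trial_log`s (or one).
#' @param include_delays Count SMR delays in the denominator.
#' @return Named numeric vector (percent) with elements `No-FES`,
#'   `Yes-FES`, and `overall`; conditions with an empty denominator are
#'   `NA`.
#' @export
semi_async_accuracy <- function(logs, include_delays = FALSE) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  if (length(logs) == 0) stop("semi_async_accuracy: no logs")
  ev <- do.call(rbind, lapply(logs, function(l) l$events))
  cond <- ifelse(ev$step %in% c("OPEN", "GRAB"), "No-FES",
                 ifelse(ev$step %in% c("STOP_FES", "HOLD"), "Yes-FES", NA))
  acc_of <- function(sel) {
    e <- ev[sel, , drop = FALSE]
    n_corr <- sum(e$outcome == "correct")
    n_err <- sum(e$outcome == "error")
    denom <- n_corr + n_err +
      if (include_delays) sum(e$outcome == "delay") else 0
    if (denom == 0) return(NA_real_)
    n_corr / denom * 100
  }
  c(`No-FES` = acc_of(!is.na(cond) & cond == "No-FES"),
    `Yes-FES` = acc_of(!is.na(cond) & cond == "Yes-FES"),
    overall = acc_of(!is.na(cond)))
}

#' Information transfer rate (Wolpaw)
#'
#' Bits per decision `B = log2(N) + P log2(P) + (1-P) log2((1-P)/(N-1))`
#' (with `0 log2 0 = 0`), scaled by the decision rate.
#'
#' @param P Accuracy as a fraction in `[0, 1]`.
#' @param N Number of classes (>= 2).
#' @param decisions_per_min Decision rate per minute.
#' @return Information transfer rate in bits/minute.
#' @export
itr <- function(P, N = 2, decisions_per_min = 60) {
  if (N < 2) stop("itr: N must be >= 2")
  if (P < 0 || P > 1) stop("itr: P must be in [0, 1]")
  xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  B <- log2(N) + xlog2(P) + (1 - P) *
    (if (P < 1) log2((1 - P) / (N - 1)) else 0)
  B * decisions_per_min
}

#' Expected accuracy of sequentially combined classifiers
#'
#' When a detection stage gates a classification stage, the chance of a
#' fully correct decision is the product of the stage accuracies; a missed
#' first stage is idle (no action), and a detected-but-misclassified window
#' is wrong.
#'
#' @param stage_accuracies Vector of per-stage accuracies in `[0, 1]`
#'   (detection first).
#' @return Named vector `(p_correct, p_idle, p_wrong)` summing to 1.
#' @export
sequential_expected_accuracy <- function(stage_accuracies) {
  if (length(stage_accuracies) == 0)
    stop("sequential_expected_accuracy: empty input")
  if (any(stage_accuracies < 0 | stage_accuracies > 1))
    stop("sequential_expected_accuracy: accuracies must be in [0, 1]")
  p_correct <- prod(stage_accuracies)
  p_idle <- 1 - stage_accuracies[1]
  p_wrong <- 1 - p_correct - p_idle
  c(p_correct = p_correct, p_idle = p_idle, p_wrong = p_wrong)
}

#' t-ratio from a summary estimate and its standard error
#' @param estimate Mean difference (or other estimate).
#' @param standard_error Its standard error (> 0).
#' @return The t-ratio `estimate / standard_error`.
#' @export
t_from_summary <- function(estimate, standard_error) {
  if (any(standard_error <= 0))
    stop("t_from_summary: standard error must be positive")
  estimate / standard_error
}

#' Two-tailed p-value from a t-ratio
#' @param t t-ratio.
#' @param df Degrees of freedom.
#' @return Two-tailed probability from the exact Student-t CDF.
#' @export
p_two_tailed <- function(t, df) 2 * stats::pt(-abs(t), df)

#' Append mean and sample-SD rows to a per-subject table
#'
#' @param table Data frame or matrix of per-subject values (rows =
#'   subjects); non-numeric columns (e.g. subject ids) are carried through.
#' @return A `summary_table`: the input with `Average` and `SD` rows
#'   appended (`SD` is `NA` for a single subject).
#' @export
aggregate_summary <- function(table) {
  df <- as.data.frame(table)
  if (nrow(df) < 1) stop("aggregate_summary: need >= 1 subject")
  num <- vapply(df, is.numeric, logical(1))
  lens <- vapply(df[num], length, integer(1))
  if (length(unique(lens)) > 1) stop("aggregate_summary: ragged table")
  avg <- df[1, , drop = FALSE]
  sdr <- df[1, , drop = FALSE]
  for (j in seq_along(df)) {
    if (num[j]) {
      avg[1, j] <- mean(df[[j]])
      sdr[1, j] <- if (nrow(df) > 1) stats::sd(df[[j]]) else NA_real_
    } else {
      avg[1, j] <- "Average"
      sdr[1, j] <- "SD"
    }
  }
  if (!any(!num)) {
    rownames(avg) <- "Average"
    rownames(sdr) <- "SD"
  }
  out <- rbind(df, avg, sdr)
  class(out) <- c("summary_table", class(out))
  out
}

#' Session-level task metrics
#'
#' Completion rate, accuracy, and ITR per FES condition and learning type
#' from a list of `trial_log`s.
#'
#' @param logs List of `trial_log`s from [run_session()].
#' @param config The session's [fsm_config()].
#' @return Data frame with one row per (learning, condition) cell.
#' @export
session_metrics <- function(logs, config = fsm_config()) {
  steps_no <- c("OPEN", "GRAB")
  steps_yes <- c("STOP_FES", "HOLD")
  rows <- list()
  for (learn in c("before", "after")) {
    sel <- vapply(logs, function(l) identical(l$learning, learn),
                  logical(1))
    if (!any(sel)) next
    sub <- logs[sel]
    for (condition in c("No-FES", "Yes-FES")) {
      steps <- if (condition == "No-FES") steps_no else steps_yes
      cr <- unlist(lapply(sub, function(l)
        vapply(steps, function(s) completion_rate(l, s, config),
               numeric(1))))
      acc <- semi_async_accuracy(sub)[[condition]]
      ev <- do.call(rbind, lapply(sub, function(l) l$events))
      ev <- ev[ev$step %in% steps, , drop = FALSE]
      n_dec <- sum(ev$outcome %in% c("correct", "error"))
      dpm <- if (n_dec > 0) {
        n_dec / (nrow(ev) * config$decision_interval / 60)
      } else 0
      rate <- if (is.na(acc)) NA_real_ else
        itr(min(max(acc / 100, 0), 1), 2, dpm)
      rows[[length(rows) + 1]] <- data.frame(
        learning = learn, condition = condition,
        completion_rate = mean(cr), accuracy = acc, itr = rate,
        n_trials = length(sub), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
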