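# Unsupervised pooled-mean (PMean) classifier adaptation: track the running
# feature mean with an exponential update and recenter the linear
# classifier's bias there, compensating slow feature-space drift without
# labels.

#' Pooled-mean adaptation state
#'
#' @param mu Initial feature-space mean (numeric vector).
#' @param eta Updating coefficient in `[0, 1]` (default 0.1).
#' @return A `pmean_state` with `mu`, `eta`, update count `t`, `bias`.
#' @export
pmean_state <- function(mu = 0, eta = 0.1) {
  if (eta < 0 || eta > 1) stop("pmean_state: eta must be in [0, 1]")
  structure(list(mu = mu, eta = eta, t = 0L, bias = NA_real_),
            class = "pmean_state")
}

#' One pooled-mean update
#'
#' Applies `mu_t = (1 - eta) mu_{t-1} + eta x` and replaces the bound
#' classifier's bias by `-w' mu_t`; the weight vector is unchanged.
#'
#' @param state A [pmean_state()].
#' @param x New feature vector (same dimension as `state$mu` and the
#'   classifier weights).
#' @param classifier A `linear_classifier` from [lda_fit()] (optional: pass
#'   `NULL` to update the mean only).
#' @return List with the updated `state` and `classifier`.
#' @export
pmean_update <- function(state, x, classifier = NULL) {
  if (length(state$mu) == 1 && length(x) > 1)
    state$mu <- rep(state$mu, length(x))
  if (length(x) != length(state$mu))
    stop("pmean_update: dimension mismatch between x and mu")
  state$mu <- (1 - state$eta) * state$mu + state$eta * x
  state$t <- state$t + 1L
  if (!is.null(classifier)) {
    if (length(classifier$w) != length(state$mu))
      stop("pmean_update: dimension mismatch between classifier and mu")
    classifier$w0 <- -sum(classifier$w * state$mu)
    state$bias <- classifier$w0
  } else {
    state$bias <- -sum(state$mu) # scalar convention when no classifier bound
  }
  list(state = state, classifier = classifier)
}

#' Should adaptation run at this point of the session?
#'
#' Adaptation starts only after the first `start_after` trials have been
#' completed: trial 10 is still static, trial 11 adapts (defaults).
#'
#' @param session_position 1-based trial index.
#' @param start_after Number of initial static trials.
#' @return `TRUE` iff `session_position > start_after`.
#' @export
adaptation_schedule <- function(session_position, start_after = 10) {
  if (any(session_position < 1))
    stop("adaptation_schedule: index must be >= 1")
  session_position > start_after
}
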