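# Synthetic EEG with motor-imagery structure.
#
# Model: per channel, 1/f-shaped Gaussian background noise plus narrowband
# mu and beta oscillators whose envelope is attenuated multiplicatively
# during the motor-imagery period (ERD), with class-specific amplitude
# modulation; stereotyped biphasic blinks on frontal channels; and a
# pulse-train stimulation artifact while FES is active.

# 1/f-shaped Gaussian noise, unit variance, length n.
one_over_f_noise <- function(n, fs, exponent) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f) # two-sided frequency axis
  gain <- ifelse(f < 0.5, 0, (pmax(f, 0.5))^(-exponent / 2))
  x <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Biphasic blink template (~300 ms), peak amplitude 1.
blink_template <- function(fs) {
  n <- round(0.3 * fs)
  t <- seq(0, 1, length.out = n)
  w <- sin(pi * t)^2
  w * sin(2 * pi * t) / max(abs(w * sin(2 * pi * t)))
}

#' Simulate one annotated 12-second trial
#'
#' Generates one multichannel EEG epoch with the canonical period layout
#' (rest 2.5 s, reference 2.5 s, motor imagery 3 s, FES initiation 1 s,
#' feedback 3 s). Sensorimotor rhythm power is present throughout; during
#' the MI period the rhythm envelope on motor channels is attenuated by the
#' class's `erd_depth`, modulated at the class's rate (SOG 1/3 Hz, FCO 1 Hz).
#' The FES pulse artifact is present during FES initiation and, when
#' `feedback_class = "KEEP"`, throughout the feedback period.
#'
#' Identical `(inputs, seed)` give bit-identical output.
#'
#' @param mi_class `"SOG"` or `"FCO"`.
#' @param feedback_class `"KEEP"` or `"STOP"`.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param trial_id Optional identifier.
#' @return A `trial_epoch`: list with `signal` (channels x samples,
#'   microvolts), `sampling_rate`, `mi_class`, `feedback_class`,
#'   `period_bounds`, `trial_id`, `seed`.
#' @export
simulate_trial <- function(mi_class, feedback_class = "STOP",
                           params = sim_params(), seed = 1,
                           trial_id = "T001") {
  mi_class <- match.arg(mi_class, c("SOG", "FCO"))
  feedback_class <- match.arg(feedback_class, c("KEEP", "STOP"))
  if (params$sampling_rate <= 0)
    stop("simulate_trial: non-positive sampling rate")
  fs <- params$sampling_rate
  n <- round(12 * fs)
  tt <- (seq_len(n) - 1) / fs
  pb <- trial_periods()

  sig <- withr::with_seed(seed, {
    nch <- params$n_channels
    out <- matrix(0, nch, n)

    # ERD envelope: 1 outside MI; inside MI attenuate by depth * m(t) where
    # m(t) is a raised-cosine modulation at the class rate in [0, 1].
    mi_idx <- tt >= 5 & tt < 8
    fmod <- params$modulation_rate[[mi_class]]
    m <- numeric(n)
    m[mi_idx] <- 0.5 * (1 - cos(2 * pi * fmod * (tt[mi_idx] - 5)))
    depth <- params$erd_depth[mi_class, ]

    for (b in list(params$mu_band, params$beta_band)) {
      # Constant-amplitude carrier at a trial-specific frequency inside the
      # band: amplitude-stable within the trial (so reference vs MI power
      # compares cleanly) while the carrier varies across trials.
      f0 <- stats::runif(1, b[1] + 0.2 * diff(b), b[2] - 0.2 * diff(b))
      phases <- stats::runif(nch, 0, 2 * pi)
      carrier <- sqrt(2) * sin(outer(phases, 2 * pi * f0 * tt, `+`))
      env <- 1 - outer(depth, m)
      out <- out + (params$rhythm_amplitude * carrier) * env
    }

    # 1/f background noise.
    for (ch in seq_len(nch)) {
      out[ch, ] <- out[ch, ] +
        params$noise_sd *
          one_over_f_noise(n, fs, params$background_exponent)
    }

    # Blinks: Poisson times, biphasic template on frontal channels.
    n_blinks <- stats::rpois(1, params$blink_rate * 12 / 60)
    if (n_blinks > 0) {
      tmpl <- blink_template(fs)
      fr <- match(frontal_channels(), params$channel_labels)
      fr <- fr[!is.na(fr)]
      fr_w <- c(1, 0.6, 0.8, 0.9, 0.8, 0.6)[seq_along(fr)]
      onsets <- sort(stats::runif(n_blinks, 0, 12 - 0.3))
      for (on in onsets) {
        idx <- round(on * fs) + seq_along(tmpl)
        idx <- idx[idx <= n]
        for (k in seq_along(fr)) {
          out[fr[k], idx] <- out[fr[k], idx] +
            params$blink_amplitude * fr_w[k] * tmpl[seq_along(idx)]
        }
      }
    }

    # FES stimulation artifact: biphasic pulse train at fes_pulse_rate,
    # present during FES initiation and during feedback when stimulation
    # continues (KEEP).
    fes_on <- tt >= 8 & tt < 9
    if (feedback_class == "KEEP") fes_on <- fes_on | (tt >= 9 & tt < 12)
    pulse_t <- seq(0, 12, by = 1 / params$fes_pulse_rate)
    pulse_idx <- round(pulse_t * fs) + 1
    pulse_idx <- pulse_idx[pulse_idx <= n - 1]
    pulse_idx <- pulse_idx[fes_on[pulse_idx]]
    if (length(pulse_idx) > 0) {
      art <- numeric(n)
      art[pulse_idx] <- 1
      art[pulse_idx + 1] <- -0.7
      # Broad spatial spread, slightly stronger over the stimulated side.
      spread <- 0.5 + 0.5 * motor_topography(params$channel_labels)
      out <- out + params$fes_artifact_amplitude * outer(spread, art)
    }
    out
  })

  rownames(sig) <- params$channel_labels
  structure(list(
    signal = sig,
    sampling_rate = fs,
    mi_class = mi_class,
    feedback_class = feedback_class,
    period_bounds = pb,
    trial_id = trial_id,
    seed = seed
  ), class = "trial_epoch")
}

#' @export
print.trial_epoch <- function(x, ...) {
  cat(sprintf("<trial_epoch %s: %s/%s, %d ch x %d samples @ %g Hz>\n",
              x$trial_id, x$mi_class, x$feedback_class,
              nrow(x$signal), ncol(x$signal), x$sampling_rate))
  invisible(x)
}

#' Generate a balanced pseudo-randomized session
#'
#' Class counts are balanced (`n_trials/2` per MI class; feedback classes
#' balanced within MI class when `n_trials` is divisible by 4) and the order
#' is pseudo-randomized by `seed`. Trial identifiers are unique.
#'
#' @param n_trials Even number of trials.
#' @inheritParams simulate_trial
#' @return List of `trial_epoch` objects.
#' @export
generate_session <- function(n_trials, params = sim_params(), seed = 1) {
  if (n_trials %% 2 != 0) stop("generate_session: n_trials must be even")
  plan <- withr::with_seed(seed, {
    half <- n_trials / 2
    mi <- c(rep("SOG", half), rep("FCO", half))
    fb <- rep(c("KEEP", "STOP"), length.out = half)
    fb <- c(fb, rep(c("STOP", "KEEP"), length.out = half))
    ord <- sample.int(n_trials)
    list(mi = mi[ord], fb = fb[ord],
         seeds = sample.int(.Machine$integer.max %/% 2, n_trials))
  })
  lapply(seq_len(n_trials), function(i) {
    simulate_trial(plan$mi[i], plan$fb[i], params, seed = plan$seeds[i],
                   trial_id = sprintf("T%03d", i))
  })
}

#' Construct a virtual subject for control-loop testing
#'
#' A virtual subject emits one scalar decision feature per 1-s window:
#' `x = s * d/2 + drift + N(0, 1)`, where `s` is the signed truth and the
#' class separation `d = 2 * qnorm(p)` is calibrated so a centered threshold
#' yields the requested per-role correct-decision probability. `drift`
#' accumulates `drift_magnitude` per trial, emulating feature-space
#' non-stationarity that pooled-mean adaptation can compensate.
#'
#' @param p_smr_detect Probability of detecting an attempted SMR per window.
#' @param p_act_correct Probability of classifying the imagery class
#'   correctly given detection.
#' @param p_fes_correct Probability of a correct keep/stop decision.
#' @param drift_magnitude Feature-space offset added per trial.
#' @param seed Integer seed stored with the subject.
#' @return A `virtual_subject` object.
#' @export
virtual_subject <- function(p_smr_detect = 0.7, p_act_correct = 0.7,
                            p_fes_correct = 0.7, drift_magnitude = 0,
                            seed = 1) {
  p <- c(SMR = p_smr_detect, ACT = p_act_correct, FES = p_fes_correct)
  if (any(p < 0 | p > 1))
    stop("virtual_subject: probabilities must be in [0, 1]")
  structure(list(p = p, drift_magnitude = drift_magnitude, seed = seed),
            class = "virtual_subject")
}

# Signed separation for probability p (finite clamp for p in {0,1}).
role_separation <- function(p) {
  if (p >= 1) return(Inf)
  if (p <= 0) return(-Inf)
  2 * stats::qnorm(p)
}

# Draw the decision feature for one window. truth_sign is +1/-1.
subject_feature <- function(subject, role, truth_sign, drift) {
  d <- role_separation(subject$p[[role]])
  if (!is.finite(d)) {
    # degenerate p: represent as an overwhelming but finite feature
    d <- sign(d) * 1e6
  }
  truth_sign * d / 2 + drift + stats::rnorm(1)
}

# Label coding per role: the "positive" label.
role_positive <- c(SMR = "DETECT", ACT = "FCO", FES = "KEEP")
role_negative <- c(SMR = "NONE", ACT = "SOG", FES = "STOP")

#' Sample one decision from a virtual subject
#'
#' Draws the subject's decision feature for the window and thresholds it at
#' `bias` (default 0, i.e. the unadapted classifier). The prediction equals
#' `truth` with the role's calibrated probability, shifted by accumulated
#' drift. Consumes the R RNG stream deterministically.
#'
#' @param subject A [virtual_subject()].
#' @param role `"SMR"`, `"ACT"`, or `"FES"`.
#' @param truth True label for the window (e.g. `"FCO"`, `"KEEP"`,
#'   `"DETECT"`).
#' @param trial_index 1-based trial number, used for drift accumulation.
#' @param bias Decision threshold (adapted classifiers move this).
#' @return Predicted label (character).
#' @export
sample_decision <- function(subject, role, truth, trial_index = 1, bias = 0) {
  role <- match.arg(role, c("SMR", "ACT", "FES"))
  pos <- role_positive[[role]]
  neg <- role_negative[[role]]
  if (!truth %in% c(pos, neg))
    stop(sprintf("sample_decision: truth '%s' invalid for role %s",
                 truth, role))
  s <- if (truth == pos) 1 else -1
  drift <- subject$drift_magnitude * (trial_index - 1)
  x <- subject_feature(subject, role, s, drift)
  if (x - bias > 0) pos else neg
}
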