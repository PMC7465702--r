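# Shared fixtures: tiny parameter sets and toy data builders. Everything is
# generated in code at test time; no stored data.

# Quiet params: no blinks, no ocular/FES confounds unless a test wants them.
quiet_params <- function(...) {
  sim_params(blink_rate = 0, ...)
}

# Params with ERD confined to a single channel at a given depth.
single_channel_erd <- function(channel = "C3", depth = 0.5) {
  p <- quiet_params()
  p$erd_depth[, ] <- 0
  p$erd_depth[, channel] <- depth
  p
}

# Two-channel toy trials with diagonal covariances (CSP oracle fixture).
diag_cov_trials <- function(n_trials, v1, v2, n_samples = 500, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n_trials), function(i)
    rbind(rnorm(n_samples, sd = sqrt(v1)),
          rnorm(n_samples, sd = sqrt(v2)))))
}

# Two well-separated Gaussian blobs in d dimensions.
gaussian_blobs <- function(n_per = 100, d = 2, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d), n_per, d))
    x[seq_len(n_per), 1] <- x[seq_len(n_per), 1] + sep
    x[n_per + seq_len(n_per), 1] <- x[n_per + seq_len(n_per), 1] - sep
    list(x = x, y = rep(c("A", "B"), each = n_per))
  })
}

# Pure sinusoid helper (channels x samples).
sinusoid <- function(freq, fs = 256, dur = 12, amp = 1) {
  matrix(amp * sin(2 * pi * freq * (seq_len(fs * dur) - 1) / fs), 1)
}

# Steady-state RMS (middle 60 % of the samples, away from filter edges).
mid_rms <- function(x) {
  n <- length(x)
  sel <- seq.int(floor(n * 0.2), ceiling(n * 0.8))
  sqrt(mean(x[sel]^2))
}

# A bare trial_epoch wrapper around a signal matrix.
as_epoch <- function(signal, fs = 256, mi_class = "SOG",
                     feedback_class = "STOP", trial_id = "T001") {
  rn <- rownames(signal)
  structure(list(signal = signal, sampling_rate = fs, mi_class = mi_class,
                 feedback_class = feedback_class,
                 period_bounds = smrfes:::trial_periods(),
                 trial_id = trial_id, seed = 0),
            class = "trial_epoch")
}
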