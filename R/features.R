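# Feature extraction: 4-Hz sub-band decomposition, ERD/ERS relative band
# power, and common spatial patterns fitted per sub-band (SBCSP) with
# score fusion.

#' The seven 4-Hz analysis sub-bands
#'
#' Contiguous 4-Hz-wide intervals tiling 1-29 Hz.
#'
#' @return List of 7 two-element Hz intervals.
#' @export
subband_set <- function() {
  lapply(seq(1, 25, by = 4), function(lo) c(lo, lo + 4))
}

#' Decompose an epoch into the seven sub-bands
#'
#' Each output is the input band-pass filtered to one sub-band with a
#' common-length zero-phase FIR, so the seven outputs sum (up to filter
#' ripple) to the 1-29 Hz band-passed input.
#'
#' @param epoch `trial_epoch` or channels x samples matrix.
#' @param bands List of Hz intervals, default [subband_set()].
#' @param fs Sampling rate for bare matrices.
#' @param n_taps FIR length shared by all bands.
#' @return List of band-filtered epochs, named by band.
#' @export
subband_decompose <- function(epoch, bands = subband_set(), fs = NULL,
                              n_taps = 385) {
  fs <- fs %||% epoch_fs(epoch)
  if (max(vapply(bands, max, numeric(1))) >= fs / 2)
    stop("subband_decompose: band above Nyquist")
  out <- lapply(bands, function(b) {
    h <- fir_bandpass_taps(fs, b[1], b[2], n_taps)
    map_signal(epoch, function(x) apply_fir(x, h))
  })
  names(out) <- vapply(bands, function(b) sprintf("%g-%g", b[1], b[2]),
                       character(1))
  out
}

#' Band power from a Hamming-windowed periodogram
#'
#' Consumes the first `n_points` samples (2.5 s at 256 Hz = 640 points),
#' applies a Hamming window per channel, and sums the window-corrected
#' periodogram bins inside each band, so that summing over 0-Nyquist
#' approximates the signal variance.
#'
#' @param segment Channels x samples matrix (or vector).
#' @param fs Sampling rate (Hz).
#' @param bands List of Hz intervals.
#' @param n_points FFT length (samples consumed).
#' @return Matrix of power values, channels x bands (microvolts squared).
#' @export
band_power <- function(segment, fs, bands = subband_set(), n_points = 640) {
  if (is.null(dim(segment))) segment <- matrix(segment, 1)
  if (ncol(segment) < n_points)
    stop("band_power: segment shorter than n_points")
  x <- segment[, seq_len(n_points), drop = FALSE]
  k <- seq_len(n_points) - 1
  w <- 0.54 - 0.46 * cos(2 * pi * k / (n_points - 1))
  xw <- sweep(x, 2, w, `*`)
  spec <- t(apply(xw, 1, function(r) Mod(stats::fft(r))^2))
  freqs <- k * fs / n_points
  denom <- n_points * sum(w^2)
  out <- matrix(0, nrow(x), length(bands))
  for (j in seq_along(bands)) {
    b <- bands[[j]]
    sel <- freqs >= b[1] & freqs < b[2] & freqs <= fs / 2
    out[, j] <- 2 * rowSums(spec[, sel, drop = FALSE]) / denom
  }
  rownames(out) <- rownames(segment)
  colnames(out) <- names(bands) %||%
    vapply(bands, function(b) sprintf("%g-%g", b[1], b[2]), character(1))
  out
}

#' Relative band power change (ERD/ERS)
#'
#' `(A - R) / R * 100`: negative values are event-related
#' desynchronization (power loss during the task), positive values
#' synchronization.
#'
#' @param reference_power Reference-period power (R), positive.
#' @param activity_power Task-period power (A), same shape.
#' @return Percent change, same shape as the inputs.
#' @export
erds <- function(reference_power, activity_power) {
  if (any(reference_power <= 0))
    stop("erds: reference power must be positive")
  (activity_power - reference_power) / reference_power * 100
}

#' ERD/ERS map over a set of trials
#'
#' Averages reference-period and MI-period band power over trials (power
#' first, then the ratio) and returns the percent change per channel and
#' sub-band.
#'
#' @param trials List of `trial_epoch` objects.
#' @param bands Sub-band list.
#' @param n_points Periodogram length (640 = 2.5 s at 256 Hz).
#' @return An `erds_map`: list with `values` (percent, channels x bands),
#'   `reference_power`, `activity_power`.
#' @export
erds_map <- function(trials, bands = subband_set(), n_points = 640) {
  fs <- trials[[1]]$sampling_rate
  acc <- function(period) {
    mats <- lapply(trials, function(e)
      band_power(period_segment(e, period), fs, bands, n_points))
    Reduce(`+`, mats) / length(mats)
  }
  R <- acc("reference")
  A <- acc("mi")
  structure(list(values = erds(R, A), reference_power = R,
                 activity_power = A),
            class = "erds_map")
}

#' Write an ERD/ERS map as CSV (channel x band)
#' @param map An `erds_map`.
#' @param path Output file.
#' @export
write_erds_map <- function(map, path) {
  df <- data.frame(channel = rownames(map$values), map$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Trace-normalized covariance of one trial matrix (channels x samples).
normalized_cov <- function(x) {
  c0 <- tcrossprod(x)
  c0 / sum(diag(c0))
}

#' Fit common spatial patterns
#'
#' Per-trial trace-normalized covariances are averaged within class; the
#' composite covariance is whitened by its eigendecomposition and the
#' whitened class-1 covariance eigendecomposed, giving a projection matrix
#' `W` whose rows are ordered by descending class-1 generalized eigenvalue.
#' The first and last `selected_pairs` rows carry the most discriminative
#' variance contrast.
#'
#' @param trials_class1,trials_class2 Lists of `trial_epoch`s or channels x
#'   samples matrices (>= 2 per class).
#' @param selected_pairs Number of filter pairs to retain.
#' @return A `csp_model`: class covariances `C1`, `C2`, composite `Cc`,
#'   whitening eigendecomposition (`Uc`, `lambda`), projection `W`,
#'   `eigenvalues` (class-1 generalized eigenvalues per filter),
#'   `selected_pairs`, `selected_rows`.
#' @export
csp_fit <- function(trials_class1, trials_class2, selected_pairs = 1) {
  as_mat <- function(e) if (inherits(e, "trial_epoch")) e$signal else
    as.matrix(e)
  m1 <- lapply(trials_class1, as_mat)
  m2 <- lapply(trials_class2, as_mat)
  if (length(m1) < 2 || length(m2) < 2)
    stop("csp_fit: need >= 2 trials per class")
  if (nrow(m1[[1]]) < 2) stop("csp_fit: need >= 2 channels")
  avg_cov <- function(ms) Reduce(`+`, lapply(ms, normalized_cov)) /
    length(ms)
  C1 <- avg_cov(m1)
  C2 <- avg_cov(m2)
  Cc <- C1 + C2
  eg <- eigen(Cc, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < 1e-8 * sum(lam)) {
    Cc <- Cc + 1e-8 * sum(diag(Cc)) * diag(nrow(Cc))
    eg <- eigen(Cc, symmetric = TRUE)
    lam <- eg$values
    message("csp_fit: composite covariance regularized")
  }
  P <- diag(1 / sqrt(lam)) %*% t(eg$vectors)   # whitening
  S1 <- P %*% C1 %*% t(P)
  eb <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  W <- t(eb$vectors) %*% P                     # rows ordered by desc lambda1
  n <- nrow(W)
  sel <- c(seq_len(selected_pairs), n - seq_len(selected_pairs) + 1)
  structure(list(C1 = C1, C2 = C2, Cc = Cc, Uc = eg$vectors, lambda = lam,
                 W = W, eigenvalues = eb$values,
                 selected_pairs = selected_pairs, selected_rows = sel,
                 n_channels = n),
            class = "csp_model")
}

#' Log-variance CSP features for one epoch
#'
#' Projects the epoch through the retained CSP filters and returns the log
#' of the variance of each projected time course.
#'
#' @param model A [csp_fit()] model.
#' @param epoch `trial_epoch` or matrix with the model's channel count.
#' @return Numeric feature vector of length `2 * selected_pairs`.
#' @export
csp_features <- function(model, epoch) {
  x <- if (inherits(epoch, "trial_epoch")) epoch$signal else as.matrix(epoch)
  if (nrow(x) != model$n_channels)
    stop("csp_features: channel count mismatch")
  proj <- model$W[model$selected_rows, , drop = FALSE] %*% x
  v <- apply(proj, 1, stats::var)
  if (any(v <= 0)) stop("csp_features: degenerate input (zero variance)")
  log(v)
}

#' Fuse per-sub-band classifier scores
#'
#' Weighted sum of the seven per-band scores; the sign of the fused score
#' gives the class decision (exact ties resolve to the first class, SOG).
#'
#' @param band_scores Numeric vector of 7 signed scores.
#' @param weights Non-negative weights summing to 1 (default equal).
#' @return The fused score (scalar).
#' @export
sbcsp_fuse <- function(band_scores, weights = rep(1 / 7, 7)) {
  if (length(band_scores) != length(weights))
    stop("sbcsp_fuse: weight-length mismatch")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("sbcsp_fuse: weights must be >= 0 and sum to 1")
  sum(weights * band_scores)
}

# Decision from a fused score: ties (exactly 0) resolve to SOG.
fused_decision <- function(score, labels = c("FCO", "SOG")) {
  if (score > 0) labels[1] else labels[2]
}

#' Fit a full sub-band CSP (SBCSP) decoder
#'
#' For each of the seven sub-bands: band-pass the training trials, fit CSP,
#' extract log-variance features, and train an LDA scorer. Fusion weights
#' default to the softmax of per-band cross-validated accuracies, so
#' informative bands dominate the fused score.
#'
#' @param trials List of `trial_epoch`s or matrices.
#' @param labels Class label per trial (`"SOG"`/`"FCO"` or any 2 levels).
#' @param period Period to extract from trial epochs (`"mi"` typically);
#'   `NULL` uses the whole matrix.
#' @param selected_pairs CSP pairs per band.
#' @param k Folds for the weight cross-validation.
#' @param seed Fold seed.
#' @param weight_temp Softmax temperature for the fusion weights.
#' @return An `sbcsp_model` with per-band CSP + LDA members and `weights`.
#' @export
sbcsp_fit <- function(trials, labels, period = "mi", selected_pairs = 1,
                      k = 10, seed = 1, weight_temp = 0.05) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("sbcsp_fit: need exactly two classes")
  # order levels so FCO (positive) comes first when present
  if ("FCO" %in% lev) lev <- c("FCO", setdiff(lev, "FCO"))
  mats <- lapply(trials, function(e) {
    if (inherits(e, "trial_epoch") && !is.null(period))
      period_segment(e, period)
    else if (inherits(e, "trial_epoch")) e$signal
    else as.matrix(e)
  })
  fs <- epoch_fs(trials[[1]])
  bands <- subband_set()
  members <- vector("list", length(bands))
  accs <- numeric(length(bands))
  for (j in seq_along(bands)) {
    h <- fir_bandpass_taps(fs, bands[[j]][1], bands[[j]][2], 385)
    filt <- lapply(mats, apply_fir, h = h)
    model <- csp_fit(filt[labels == lev[1]], filt[labels == lev[2]],
                     selected_pairs)
    feats <- t(vapply(filt, function(m) csp_features(model, m),
                      numeric(2 * selected_pairs)))
    clf <- lda_fit(feats, labels, positive = lev[1])
    k_eff <- max(2, min(k, min(table(labels))))
    cv <- crossval_accuracy(feats, labels, k = k_eff, seed = seed,
                            method = "lda")
    members[[j]] <- list(band = bands[[j]], csp = model, lda = clf)
    accs[j] <- cv$mean_accuracy
  }
  if (any(!is.finite(accs))) accs[!is.finite(accs)] <- 0.5
  w <- exp((accs - max(accs)) / weight_temp)
  w <- w / sum(w)
  structure(list(members = members, weights = w, cv_accuracies = accs,
                 levels = lev, fs = fs, period = period,
                 selected_pairs = selected_pairs),
            class = "sbcsp_model")
}

#' Score an epoch with an SBCSP decoder
#'
#' @param model An [sbcsp_fit()] model.
#' @param epoch `trial_epoch` or channels x samples matrix.
#' @return List with `band_scores` (7 signed LDA scores), `fused_score`,
#'   and `decision` (a model level; positive score = first level).
#' @export
sbcsp_score <- function(model, epoch) {
  x <- if (inherits(epoch, "trial_epoch") && !is.null(model$period))
    period_segment(epoch, model$period)
  else if (inherits(epoch, "trial_epoch")) epoch$signal
  else as.matrix(epoch)
  scores <- vapply(model$members, function(m) {
    h <- fir_bandpass_taps(model$fs, m$band[1], m$band[2], 385)
    f <- csp_features(m$csp, apply_fir(x, h))
    lda_score(m$lda, f)
  }, numeric(1))
  fused <- sbcsp_fuse(scores, model$weights)
  list(band_scores = scores, fused_score = fused,
       decision = fused_decision(fused, model$levels))
}
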