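# Preprocessing chain: 60 Hz notch, trial rejection (amplitude / entropy /
# kurtosis), 1-29 Hz band-pass, PCA dimensionality reduction at 95 %
# explained variance, ICA cleaning (offline only), small surface Laplacian.

#' Filter specification
#'
#' @param notch_freq Mains frequency to notch out (Hz).
#' @param bandpass Two-element Hz interval for the analysis band-pass.
#' @param filter_family `"FIR"` (Hamming windowed-sinc, zero-phase) or
#'   `"IIR"` (biquad cascade, zero-phase forward-backward); the band-pass is
#'   FIR by design, the notch IIR.
#' @param order FIR tap count; default scales with the low edge so the
#'   transition band stays below the low cutoff.
#' @param notch_q Quality factor of the IIR notch.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(notch_freq = 60, bandpass = c(1, 29),
                        filter_family = "FIR", order = NULL, notch_q = 30) {
  if (bandpass[1] <= 0 || bandpass[1] >= bandpass[2])
    stop("filter_spec: need 0 < low edge < high edge")
  structure(list(notch_freq = notch_freq, bandpass = bandpass,
                 filter_family = filter_family, order = order,
                 notch_q = notch_q),
            class = "filter_spec")
}

# Apply a function to the signal matrix of an epoch (or a bare matrix).
map_signal <- function(epoch, f) {
  if (inherits(epoch, "trial_epoch")) {
    epoch$signal <- f(epoch$signal)
    epoch
  } else {
    f(as.matrix(epoch))
  }
}

epoch_fs <- function(epoch, default = 256) {
  if (inherits(epoch, "trial_epoch")) epoch$sampling_rate else default
}

#' Notch filter (zero-phase IIR biquad)
#'
#' Attenuates the mains component by >= 20 dB while leaving the passband
#' within +/- 1 dB.
#'
#' @param epoch A `trial_epoch` or channels x samples matrix.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate, required only for bare matrices.
#' @return Filtered epoch/matrix of the same shape.
#' @export
notch_filter <- function(epoch, spec = filter_spec(), fs = NULL) {
  fs <- fs %||% epoch_fs(epoch)
  if (spec$notch_freq >= fs / 2)
    stop("notch_filter: notch frequency must be below Nyquist")
  co <- notch_coefficients(fs, spec$notch_freq, spec$notch_q)
  map_signal(epoch, function(x) apply_iir_filtfilt(x, co$b, co$a))
}

default_fir_order <- function(fs, lo) {
  # transition width ~ 3.3 * fs / n_taps; keep it under the low edge
  max(101, 2 * floor(3.3 * fs / (2 * lo)) + 1)
}

#' Band-pass filter (zero-phase FIR)
#'
#' Hamming windowed-sinc design; stopband (DC and beyond the high edge)
#' attenuated >= 20 dB, passband within +/- 1 dB.
#'
#' @inheritParams notch_filter
#' @param band Optional override of `spec$bandpass`.
#' @return Filtered epoch/matrix.
#' @export
bandpass_filter <- function(epoch, spec = filter_spec(), fs = NULL,
                            band = NULL) {
  fs <- fs %||% epoch_fs(epoch)
  band <- band %||% spec$bandpass
  if (band[2] >= fs / 2)
    stop("bandpass_filter: high edge must be below Nyquist")
  n_taps <- spec$order %||% default_fir_order(fs, band[1])
  h <- fir_bandpass_taps(fs, band[1], band[2], n_taps)
  map_signal(epoch, function(x) apply_fir(x, h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shannon entropy of the 20-bin amplitude histogram (nats).
amplitude_entropy <- function(x, bins = 20) {
  h <- tabulate(cut(x, breaks = bins, labels = FALSE), nbins = bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log(p))
}

sample_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

#' Automatic trial rejection
#'
#' A trial is rejected if any sample magnitude exceeds `amplitude_limit`
#' (microvolts), or if the z-score across the session of its amplitude
#' histogram entropy or its excess kurtosis exceeds `z_limit` in absolute
#' value. Reasons are recorded with priority amplitude > kurtosis > entropy
#' (a trial can trip several criteria; the report names one).
#'
#' @param session Non-empty list of `trial_epoch` objects.
#' @param amplitude_limit Large-fluctuation threshold (microvolts).
#' @param z_limit Probability threshold in standard deviations.
#' @return A `rejection_report`: list with `kept_ids`, `rejected`
#'   (data.frame trial_id / reason / statistic), and `thresholds`.
#' @export
reject_trials <- function(session, amplitude_limit = 150, z_limit = 3) {
  if (length(session) == 0) stop("reject_trials: empty session")
  ids <- vapply(session, function(e) e$trial_id, character(1))
  amp <- vapply(session, function(e) max(abs(e$signal)), numeric(1))
  ent <- vapply(session, function(e) amplitude_entropy(as.numeric(e$signal)),
                numeric(1))
  kur <- vapply(session, function(e) sample_kurtosis(as.numeric(e$signal)),
                numeric(1))
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  ze <- zs(ent)
  zk <- zs(kur)
  reason <- rep(NA_character_, length(session))
  statv <- rep(NA_real_, length(session))
  hit <- function(cond, nm, v) {
    new <- cond & is.na(reason)
    reason[new] <<- nm
    statv[new] <<- v[new]
  }
  hit(amp > amplitude_limit, "amplitude", amp)
  hit(abs(zk) > z_limit, "kurtosis", zk)
  hit(abs(ze) > z_limit, "entropy", ze)
  rej <- !is.na(reason)
  structure(list(
    kept_ids = ids[!rej],
    rejected = data.frame(trial_id = ids[rej], reason = reason[rej],
                          statistic = statv[rej], stringsAsFactors = FALSE),
    thresholds = c(amplitude = amplitude_limit, z = z_limit)
  ), class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report: %d kept, %d rejected>\n",
              length(x$kept_ids), nrow(x$rejected)))
  if (nrow(x$rejected)) print(x$rejected)
  invisible(x)
}

#' Write a rejection report as CSV
#' @param report A `rejection_report`.
#' @param path Output file.
#' @export
write_rejection_report <- function(report, path) {
  df <- report$rejected
  df$amplitude_limit <- report$thresholds[["amplitude"]]
  df$z_limit <- report$thresholds[["z"]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' PCA dimensionality reduction over channels
#'
#' Fits channel-space principal components on the concatenated epochs and
#' retains the smallest number of components whose cumulative explained
#' variance reaches `threshold`.
#'
#' @param epochs List of `trial_epoch` objects (or matrices).
#' @param threshold Explained-variance fraction in (0, 1].
#' @return List with `model` (class `pca_model`: `component_basis`,
#'   `explained_variance_ratio`, `retained_count`, `threshold`, `center`)
#'   and `epochs`, the projected data (retained components x samples).
#' @export
pca_fit_project <- function(epochs, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1)
    stop("pca_fit_project: threshold must be in (0, 1]")
  raw <- lapply(epochs, function(e)
    if (inherits(e, "trial_epoch")) e$signal else as.matrix(e))
  big <- do.call(cbind, raw)
  if (nrow(big) < 2 || ncol(big) < 2)
    stop("pca_fit_project: need >= 2 channels and >= 2 samples")
  ctr <- rowMeans(big)
  bc <- big - ctr
  cv <- tcrossprod(bc) / (ncol(bc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  ratio <- ev / sum(ev)
  k <- which(cumsum(ratio) >= threshold - 1e-12)[1]
  basis <- eg$vectors[, seq_len(k), drop = FALSE]
  model <- structure(list(component_basis = basis,
                          explained_variance_ratio = ratio,
                          retained_count = k, threshold = threshold,
                          center = ctr),
                     class = "pca_model")
  project <- function(m) t(basis) %*% (m - ctr)
  reduced <- lapply(epochs, function(e) {
    if (inherits(e, "trial_epoch")) {
      e$signal <- project(e$signal)
      rownames(e$signal) <- paste0("PC", seq_len(k))
      e
    } else project(as.matrix(e))
  })
  list(model = model, epochs = reduced)
}

# --- FastICA-style symmetric fixed-point ICA -------------------------------

fastica_fit <- function(x, n_comp = nrow(x), max_iter = 200, tol = 1e-6,
                        seed = 42) {
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- tcrossprod(xc) / (ncol(xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  n_comp <- min(n_comp, sum(keep))
  d <- eg$values[seq_len(n_comp)]
  e <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  wh <- diag(1 / sqrt(d), n_comp) %*% t(e)      # whitening
  dw <- e %*% diag(sqrt(d), n_comp)             # dewhitening
  z <- wh %*% xc
  w <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_comp^2), n_comp)
    qr.Q(qr(m))
  })
  sym_orth <- function(w) {
    s <- w %*% t(w)
    es <- eigen(s, symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-12)),
                        n_comp) %*% t(es$vectors) %*% w
  }
  w <- sym_orth(w)
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    w_new <- g %*% t(z) / ncol(z) - diag(rowMeans(gp), n_comp) %*% w
    w_new <- sym_orth(w_new)
    if (max(abs(abs(rowSums(w_new * w)) - 1)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  unmixing <- w %*% wh
  mixing <- dw %*% t(w)
  list(unmixing = unmixing, mixing = mixing, center = ctr,
       sources = unmixing %*% xc)
}

#' ICA cleaning of artifact components (offline only)
#'
#' Decomposes the concatenated epochs into maximally independent components
#' (FastICA-style symmetric fixed point, tanh contrast), flags components
#' whose time course correlates with the frontal-channel template above
#' `cor_threshold` in absolute value, removes them, and reconstructs the
#' signal from the remaining components.
#'
#' @param epochs List of `trial_epoch` objects or matrices (channels x
#'   samples), all with the same channel set.
#' @param template Artifact reference time course over the concatenated
#'   samples. Defaults to the mean of frontal channels when the data carry
#'   the standard labels.
#' @param cor_threshold Absolute-correlation flagging threshold.
#' @param online Set `TRUE` to signal online mode; refused (ICA is an
#'   offline-only stage).
#' @param seed Seed for the ICA initialization.
#' @return List with `epochs` (cleaned) and `model` (class `ica_model`:
#'   `unmixing`, `mixing`, `component_flags`, `criterion_scores`).
#' @export
ica_clean <- function(epochs, template = NULL, cor_threshold = 0.7,
                      online = FALSE, seed = 42) {
  if (online) stop("ica_clean: offline only")
  raw <- lapply(epochs, function(e)
    if (inherits(e, "trial_epoch")) e$signal else as.matrix(e))
  big <- do.call(cbind, raw)
  if (nrow(big) < 2) {
    warning("ica_clean: fewer than 2 components; pass-through")
    return(list(epochs = epochs, model = NULL))
  }
  if (is.null(template)) {
    fr <- match(frontal_channels(), rownames(big))
    fr <- fr[!is.na(fr)]
    if (length(fr) == 0)
      stop("ica_clean: no template given and no frontal channels found")
    template <- colMeans(big[fr, , drop = FALSE])
  }
  fit <- fastica_fit(big, seed = seed)
  scores <- abs(apply(fit$sources, 1, stats::cor, y = template))
  flags <- scores > cor_threshold
  model <- structure(list(unmixing = fit$unmixing, mixing = fit$mixing,
                          component_flags = ifelse(flags, "artifact",
                                                   "neural"),
                          criterion_scores = scores),
                     class = "ica_model")
  if (!any(flags)) return(list(epochs = epochs, model = model))
  keep <- !flags
  clean_big <- fit$mixing[, keep, drop = FALSE] %*%
    fit$sources[keep, , drop = FALSE] + fit$center
  # split back into epochs
  sizes <- vapply(raw, ncol, integer(1))
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1
  cleaned <- lapply(seq_along(epochs), function(i) {
    seg <- clean_big[, starts[i]:stops[i], drop = FALSE]
    rownames(seg) <- rownames(raw[[i]])
    if (inherits(epochs[[i]], "trial_epoch")) {
      e <- epochs[[i]]
      e$signal <- seg
      e
    } else seg
  })
  list(epochs = cleaned, model = model)
}

#' Small surface Laplacian
#'
#' Replaces each channel by itself minus the mean of its montage neighbors,
#' sharpening focal sources. By default only the reference and MI periods
#' are transformed (the segment feeding the ERD/ERS analysis); pass
#' `segments = "all"` to transform the whole epoch. Channels without
#' neighbors pass through unchanged.
#'
#' @param epochs List of `trial_epoch` objects (or a single one).
#' @param montage Named list of neighbor labels, as [default_montage()].
#' @param segments `"all"` or a character vector of period names.
#' @return Epochs with Laplacian-transformed signals.
#' @export
surface_laplacian <- function(epochs, montage = default_montage(),
                              segments = c("reference", "mi")) {
  single <- inherits(epochs, "trial_epoch") || is.matrix(epochs)
  if (single) epochs <- list(epochs)
  out <- lapply(epochs, function(e) {
    sig <- if (inherits(e, "trial_epoch")) e$signal else as.matrix(e)
    labs <- rownames(sig)
    if (is.null(labs)) labs <- names(montage)[seq_len(nrow(sig))]
    lap <- sig
    for (i in seq_len(nrow(sig))) {
      nbs <- montage[[labs[i]]]
      idx <- match(nbs, labs)
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0) next # no neighbors: pass through
      lap[i, ] <- sig[i, ] - colMeans(sig[idx, , drop = FALSE])
    }
    if (inherits(e, "trial_epoch") && !identical(segments, "all")) {
      fs <- e$sampling_rate
      pb <- e$period_bounds
      sel <- pb[pb$period %in% segments, ]
      cols <- unlist(lapply(seq_len(nrow(sel)), function(r)
        seq.int(floor(sel$start[r] * fs) + 1, floor(sel$end[r] * fs))))
      e$signal[, cols] <- lap[, cols]
      e
    } else if (inherits(e, "trial_epoch")) {
      e$signal <- lap
      e
    } else lap
  })
  if (single) out[[1]] else out
}
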