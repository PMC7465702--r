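# EDF+ session reader/writer in base R. The format: a fixed-width ASCII
# header (256 bytes + 256 per signal), int16 little-endian sample records,
# and an "EDF Annotations" signal carrying time-stamped annotation lists
# (TALs) for period boundaries and class labels. One data record = 1 s.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

tal_ts <- function(onset) {
  # EDF+ requires no trailing zeros beyond need; plain format is fine
  s <- sprintf("%.3f", onset)
  if (onset >= 0) paste0("+", s) else s
}

#' Bundle epochs, montage and metadata for session I/O
#'
#' @param epochs List of `trial_epoch`s sharing sampling rate and channels.
#' @param montage Neighbor map; default derived from the channel labels.
#' @param metadata Named list (subject id, seed, free-form provenance).
#' @return A `session_bundle`.
#' @export
session_bundle <- function(epochs, montage = NULL, metadata = list()) {
  fs <- unique(vapply(epochs, function(e) e$sampling_rate, numeric(1)))
  if (length(fs) != 1)
    stop("session_bundle: epochs disagree on sampling rate")
  labs <- rownames(epochs[[1]]$signal)
  for (e in epochs)
    if (!identical(rownames(e$signal), labs))
      stop("session_bundle: epochs disagree on channel ordering")
  structure(list(epochs = epochs,
                 montage = montage %||% default_montage(labs),
                 metadata = metadata),
            class = "session_bundle")
}

#' Write a session as EDF+
#'
#' Signals are quantized to 16 bits over the physical range (default
#' +/- 200 microvolts, clipped); every period boundary and each trial's
#' class labels become EDF+ annotations.
#'
#' @param bundle A [session_bundle()] (or bare list of epochs).
#' @param path Output file.
#' @param physical_range Symmetric physical range in microvolts.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path, physical_range = 200) {
  if (!inherits(bundle, "session_bundle"))
    bundle <- session_bundle(bundle)
  epochs <- bundle$epochs
  fs <- epochs[[1]]$sampling_rate
  if (fs != round(fs)) stop("write_session: integer sampling rate required")
  nch <- nrow(epochs[[1]]$signal)
  labs <- rownames(epochs[[1]]$signal) %||% paste0("CH", seq_len(nch))
  trial_len <- 12
  n_rec <- trial_len * length(epochs)
  pmin <- -physical_range
  pmax <- physical_range
  dmin <- -32768
  dmax <- 32767
  gain <- (pmax - pmin) / (dmax - dmin)

  # --- annotation payload per record ---------------------------------------
  anns <- vector("list", n_rec)
  for (i in seq_along(epochs)) {
    e <- epochs[[i]]
    t0 <- (i - 1) * trial_len
    rec0 <- t0 + 1 # record index (1-based) at trial start
    anns[[rec0]] <- c(anns[[rec0]], sprintf(
      "%s\x15%s\x14trial %s mi=%s fb=%s seed=%d\x14",
      tal_ts(t0), sprintf("%.3f", trial_len), e$trial_id, e$mi_class,
      e$feedback_class, as.integer(e$seed)))
    pb <- e$period_bounds
    for (r in seq_len(nrow(pb))) {
      rec <- floor(t0 + pb$start[r]) + 1
      anns[[rec]] <- c(anns[[rec]], sprintf(
        "%s\x15%s\x14%s\x14", tal_ts(t0 + pb$start[r]),
        sprintf("%.3f", pb$end[r] - pb$start[r]), pb$period[r]))
    }
  }
  payloads <- vapply(seq_len(n_rec), function(r) {
    paste0(tal_ts(r - 1), "\x14\x14", paste0(unlist(anns[[r]]),
                                             collapse = ""))
  }, character(1))
  ann_bytes <- max(nchar(payloads, type = "bytes")) + 2
  if (ann_bytes %% 2 == 1) ann_bytes <- ann_bytes + 1
  ann_samples <- ann_bytes / 2

  # --- header --------------------------------------------------------------
  ns <- nch + 1
  meta <- bundle$metadata
  rec_id <- paste0("Startdate 01-JAN-2026 ",
                   meta$subject %||% "X", " ",
                   "seed_", meta$seed %||% "NA")
  header <- paste0(
    edf_pad("0", 8),
    edf_pad(meta$patient %||% "X X X X", 80),
    edf_pad(rec_id, 80),
    "01.01.26", "00.00.00",
    edf_pad(256 * (ns + 1), 8),
    edf_pad("EDF+C", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4))
  field <- function(vals, width) paste0(vapply(vals, edf_pad, "", width),
                                        collapse = "")
  sig_labels <- c(labs, "EDF Annotations")
  header <- paste0(
    header,
    field(sig_labels, 16),
    field(rep("", ns), 80),                       # transducer
    field(c(rep("uV", nch), ""), 8),              # physical dimension
    field(c(rep(pmin, nch), -1), 8),
    field(c(rep(pmax, nch), 1), 8),
    field(rep(dmin, ns), 8),
    field(rep(dmax, ns), 8),
    field(rep("", ns), 80),                       # prefiltering
    field(c(rep(fs, nch), ann_samples), 8),
    field(rep("", ns), 32))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)

  big <- do.call(cbind, lapply(epochs, function(e) e$signal))
  dig <- round((pmin(pmax(big, pmin), pmax) - pmin) / gain) + dmin
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * fs + seq_len(fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
    pay <- charToRaw(payloads[r])
    writeBin(c(pay, raw(ann_bytes - length(pay))), con)
  }
  invisible(path)
}

read_edf_header <- function(con, path) {
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256 || substr(hdr, 1, 1) != "0")
    stop("read_session: not an EDF file (bad version field): ", path)
  take <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  ns <- as.integer(take(hdr, 253, 4))
  n_rec <- as.integer(take(hdr, 237, 8))
  rec_dur <- as.numeric(take(hdr, 245, 8))
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  # offsets in bytes within the per-field blocks:
  off <- c(label = 0, transducer = 16, dim = 96, pmin = 104, pmax = 112,
           dmin = 120, dmax = 128, prefilter = 136, nsamp = 216)
  field_at <- function(name, width) {
    start <- off[[name]] * ns
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, start + (i - 1) * width + 1,
                    start + i * width)), character(1))
  }
  list(ns = ns, n_rec = n_rec, rec_dur = rec_dur,
       labels = field_at("label", 16),
       pmin = as.numeric(field_at("pmin", 8)),
       pmax = as.numeric(field_at("pmax", 8)),
       dmin = as.numeric(field_at("dmin", 8)),
       dmax = as.numeric(field_at("dmax", 8)),
       nsamp = as.integer(field_at("nsamp", 8)),
       recording = take(hdr, 89, 80))
}

#' Read an EDF+ session
#'
#' Reconstructs the `trial_epoch`s from the annotation channel (trial
#' markers with class labels, plus period boundaries). Files without an
#' annotation signal are rejected.
#'
#' @param path An EDF+ file written by [write_session()].
#' @return A `session_bundle`.
#' @export
read_session <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con, path)
  ann_idx <- which(h$labels == "EDF Annotations")
  if (length(ann_idx) != 1)
    stop("read_session: missing annotation channel (byte offset 256, ",
         "signal labels): ", path)
  eeg_idx <- setdiff(seq_len(h$ns), ann_idx)
  gains <- (h$pmax - h$pmin) / (h$dmax - h$dmin)
  sig <- vector("list", h$ns)
  for (i in eeg_idx) sig[[i]] <- numeric(h$n_rec * h$nsamp[i])
  ann_text <- character(h$n_rec)
  for (r in seq_len(h$n_rec)) {
    for (i in seq_len(h$ns)) {
      n <- h$nsamp[i]
      if (i == ann_idx) {
        bytes <- readBin(con, "raw", n * 2)
        ann_text[r] <- rawToChar(bytes[bytes != as.raw(0)])
      } else {
        d <- readBin(con, "integer", n, size = 2, endian = "little")
        sig[[i]][(r - 1) * n + seq_len(n)] <-
          (d - h$dmin[i]) * gains[i] + h$pmin[i]
      }
    }
  }
  mat <- do.call(rbind, sig[eeg_idx])
  rownames(mat) <- h$labels[eeg_idx]
  fs <- h$nsamp[eeg_idx[1]] / h$rec_dur

  # parse TALs: split on \x14\x00? payload already stripped of NULs; TALs
  # separated by \x14 terminators.
  tals <- unlist(strsplit(paste0(ann_text, collapse = "\x01"), "\x01"))
  events <- list()
  for (chunk in tals) {
    parts <- strsplit(chunk, "\x14")[[1]]
    if (length(parts) < 2) next
    # parts[1] is "+onset" or "+onset\x15dur"; subsequent TALs concatenated
    i <- 1
    while (i <= length(parts)) {
      head <- strsplit(parts[i], "\x15")[[1]]
      onset <- suppressWarnings(as.numeric(head[1]))
      dur <- if (length(head) > 1)
        suppressWarnings(as.numeric(head[2])) else NA_real_
      txt <- if (i + 1 <= length(parts)) parts[i + 1] else ""
      if (!is.na(onset) && nzchar(txt))
        events[[length(events) + 1]] <- list(onset = onset, duration = dur,
                                             text = txt)
      i <- i + 2
    }
  }
  ev <- do.call(rbind, lapply(events, function(e)
    data.frame(onset = e$onset, duration = e$duration, text = e$text,
               stringsAsFactors = FALSE)))
  trials <- ev[grepl("^trial ", ev$text), , drop = FALSE]
  if (nrow(trials) == 0) stop("read_session: no trial annotations: ", path)
  trials <- trials[order(trials$onset), , drop = FALSE]
  epochs <- lapply(seq_len(nrow(trials)), function(k) {
    m <- regmatches(trials$text[k],
                    regexec("^trial (\\S+) mi=(\\S+) fb=(\\S+) seed=(\\S+)",
                            trials$text[k]))[[1]]
    t0 <- trials$onset[k]
    idx <- round(t0 * fs) + seq_len(round(12 * fs))
    per <- ev[ev$text %in% trial_periods()$period &
                ev$onset >= t0 - 1e-9 & ev$onset < t0 + 12, , drop = FALSE]
    pb <- if (nrow(per) == 5) {
      per <- per[order(per$onset), ]
      data.frame(period = per$text, start = per$onset - t0,
                 end = per$onset - t0 + per$duration,
                 stringsAsFactors = FALSE)
    } else trial_periods()
    structure(list(signal = mat[, idx, drop = FALSE],
                   sampling_rate = fs, mi_class = m[3],
                   feedback_class = m[4],
                   period_bounds = pb, trial_id = m[2],
                   seed = suppressWarnings(as.integer(m[5]))),
              class = "trial_epoch")
  })
  md <- list(recording = h$recording)
  sd_match <- regmatches(h$recording, regexec("seed_(\\d+)", h$recording))[[1]]
  if (length(sd_match) == 2) md$seed <- as.integer(sd_match[2])
  session_bundle(epochs, metadata = md)
}
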