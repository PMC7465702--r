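#' Standard 32-channel montage labels
#'
#' The 10-10 electrode labels of the 32-channel active-electrode cap used by
#' the acquisition setup the pipeline models (ground Fpz, left-earlobe
#' reference).
#'
#' @return Character vector of 32 channel labels.
#' @export
standard_channels <- function() {
  c("AFz", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
    "T7", "C5", "C3", "Cz", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CPz", "CP4", "CP6", "TP8",
    "P3", "P4", "PO3", "PO4", "O1", "O2")
}

# Frontal channels carrying ocular activity in the default montage.
frontal_channels <- function() c("AFz", "F7", "F3", "Fz", "F4", "F8")

#' Default electrode neighbor map for the small surface Laplacian
#'
#' Nearest-neighbor sets on the 32-channel montage, used by
#' [surface_laplacian()]. Channels at the cap edge have fewer neighbors.
#'
#' @param labels Channel labels; defaults to [standard_channels()].
#' @return Named list mapping each label to its neighbor labels.
#' @export
default_montage <- function(labels = standard_channels()) {
  nb <- list(
    AFz = c("F3", "Fz", "F4"),
    F7  = c("F3", "FC5", "T7"),
    F3  = c("F7", "Fz", "FC5", "FC3", "FC1", "AFz"),
    Fz  = c("F3", "F4", "FC1", "FC2", "AFz"),
    F4  = c("Fz", "F8", "FC2", "FC4", "FC6", "AFz"),
    F8  = c("F4", "FC6", "T8"),
    FC5 = c("F7", "F3", "FC3", "T7", "C5"),
    FC3 = c("F3", "FC5", "FC1", "C5", "C3"),
    FC1 = c("F3", "Fz", "FC3", "FC2", "C3", "Cz"),
    FC2 = c("Fz", "F4", "FC1", "FC4", "Cz", "C4"),
    FC4 = c("F4", "FC2", "FC6", "C4", "C6"),
    FC6 = c("F4", "F8", "FC4", "C6", "T8"),
    T7  = c("F7", "FC5", "C5", "TP7"),
    C5  = c("FC5", "FC3", "T7", "C3", "TP7", "CP5"),
    C3  = c("FC3", "FC1", "C5", "Cz", "CP5", "CP3"),
    Cz  = c("FC1", "FC2", "C3", "C4", "CP3", "CPz", "CP4"),
    C4  = c("FC2", "FC4", "Cz", "C6", "CP4", "CP6"),
    C6  = c("FC4", "FC6", "C4", "T8", "CP6", "TP8"),
    T8  = c("F8", "FC6", "C6", "TP8"),
    TP7 = c("T7", "C5", "CP5"),
    CP5 = c("C5", "C3", "TP7", "CP3", "P3"),
    CP3 = c("C3", "Cz", "CP5", "CPz", "P3"),
    CPz = c("Cz", "CP3", "CP4", "P3", "P4"),
    CP4 = c("Cz", "C4", "CPz", "CP6", "P4"),
    CP6 = c("C4", "C6", "CP4", "TP8", "P4"),
    TP8 = c("C6", "T8", "CP6"),
    P3  = c("CP5", "CP3", "CPz", "PO3", "O1"),
    P4  = c("CPz", "CP4", "CP6", "PO4", "O2"),
    PO3 = c("P3", "O1"),
    PO4 = c("P4", "O2"),
    O1  = c("P3", "PO3", "O2"),
    O2  = c("P4", "PO4", "O1")
  )
  nb[intersect(names(nb), labels)]
}

# Spatial weight of the sensorimotor rhythm over the scalp: strongest at
# C3/CP3 (contralateral hand area for an assumed right-hand task),
# configurable via sim_params(rhythm_amplitude=).
motor_topography <- function(labels = standard_channels(),
                             center = c("C3", "CP3")) {
  w <- rep(0.1, length(labels))
  names(w) <- labels
  primary <- intersect(center, labels)
  secondary <- unique(unlist(default_montage(labels)[primary]))
  w[secondary] <- 0.45
  w[primary] <- 1
  w
}

#' Simulation parameters for the synthetic EEG generator
#'
#' Collects every tunable of the generator in one validated object. Defaults
#' encode the acquisition and task structure the pipeline assumes: 32 channels
#' at 256 Hz, mu (8-12 Hz) and beta (18-26 Hz) sensorimotor rhythms over
#' C3/CP3, event-related desynchronization (ERD) expressed as multiplicative
#' attenuation of the rhythm envelope during motor imagery, slow one-time
#' grasping (SOG, 1/3 Hz) versus fast cyclic opening (FCO, 1 Hz) amplitude
#' modulation, Poisson eye blinks on frontal channels, and an FES pulse-train
#' artifact during stimulation.
#'
#' @param sampling_rate Samples per second (Hz).
#' @param channel_labels Channel labels (no duplicates).
#' @param background_exponent Spectral slope of the 1/f background noise.
#' @param mu_band,beta_band Two-element Hz intervals inside 1-29 Hz.
#' @param rhythm_amplitude Rhythm RMS amplitude per channel (microvolts);
#'   scalar values are spread over the motor topography.
#' @param erd_depth Attenuation fraction in `[0,1]` of the rhythm envelope
#'   during motor imagery, as a 2 x n_channels matrix with rows `SOG`, `FCO`.
#'   Scalars/vectors are expanded over the motor topography.
#' @param modulation_rate Named vector of amplitude-modulation rates (Hz)
#'   for the two imagery classes (defaults SOG = 1/3, FCO = 1).
#' @param blink_rate Eye-blink events per minute.
#' @param blink_amplitude Blink peak amplitude (microvolts) on frontal
#'   channels.
#' @param fes_artifact_amplitude Stimulation-artifact pulse amplitude
#'   (microvolts); default 10x the peak rhythm amplitude.
#' @param fes_pulse_rate Stimulation pulse rate (Hz).
#' @param noise_sd Standard deviation (microvolts) of the 1/f background
#'   per channel.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(sampling_rate = 256,
                       channel_labels = standard_channels(),
                       background_exponent = 1,
                       mu_band = c(8, 12),
                       beta_band = c(18, 26),
                       rhythm_amplitude = 5,
                       erd_depth = NULL,
                       modulation_rate = c(SOG = 1 / 3, FCO = 1),
                       blink_rate = 4,
                       blink_amplitude = 80,
                       fes_artifact_amplitude = NULL,
                       fes_pulse_rate = 35,
                       noise_sd = 10) {
  if (sampling_rate <= 0) stop("sim_params: sampling_rate must be positive")
  if (anyDuplicated(channel_labels))
    stop("sim_params: channel_labels must be unique")
  n_ch <- length(channel_labels)
  check_band <- function(b, nm) {
    if (length(b) != 2 || b[1] >= b[2] || b[1] < 1 || b[2] > 29)
      stop(sprintf("sim_params: %s must lie inside 1-29 Hz", nm))
  }
  check_band(mu_band, "mu_band")
  check_band(beta_band, "beta_band")

  topo <- motor_topography(channel_labels)
  if (length(rhythm_amplitude) == 1) {
    rhythm_amplitude <- rhythm_amplitude * topo
  }
  if (length(rhythm_amplitude) != n_ch)
    stop("sim_params: rhythm_amplitude must be scalar or one value per channel")
  names(rhythm_amplitude) <- channel_labels

  if (is.null(erd_depth)) {
    # SOG (slow grasp) produces a deeper desynchronization than FCO in this
    # model; the magnitude difference is what makes the classes separable.
    erd_depth <- rbind(SOG = 0.6 * topo, FCO = 0.25 * topo)
  } else if (is.null(dim(erd_depth)) && length(erd_depth) == 1) {
    erd_depth <- rbind(SOG = erd_depth * topo / max(topo),
                       FCO = erd_depth * topo / max(topo))
  }
  if (!is.matrix(erd_depth) || nrow(erd_depth) != 2 || ncol(erd_depth) != n_ch)
    stop("sim_params: erd_depth must be a 2 x n_channels matrix (SOG, FCO)")
  rownames(erd_depth) <- c("SOG", "FCO")
  colnames(erd_depth) <- channel_labels
  if (any(erd_depth < 0 | erd_depth > 1))
    stop("sim_params: erd_depth entries must be in [0, 1]")

  if (is.null(fes_artifact_amplitude))
    fes_artifact_amplitude <- 10 * max(rhythm_amplitude)

  structure(list(
    sampling_rate = sampling_rate,
    n_channels = n_ch,
    channel_labels = channel_labels,
    background_exponent = background_exponent,
    mu_band = mu_band,
    beta_band = beta_band,
    rhythm_amplitude = rhythm_amplitude,
    erd_depth = erd_depth,
    modulation_rate = modulation_rate,
    blink_rate = blink_rate,
    blink_amplitude = blink_amplitude,
    fes_artifact_amplitude = fes_artifact_amplitude,
    fes_pulse_rate = fes_pulse_rate,
    noise_sd = noise_sd
  ), class = "sim_params")
}

# Canonical trial layout: five contiguous half-open periods covering [0, 12).
trial_periods <- function() {
  data.frame(
    period = c("rest", "reference", "mi", "fes_init", "feedback"),
    start = c(0, 2.5, 5, 8, 9),
    end = c(2.5, 5, 8, 9, 12),
    stringsAsFactors = FALSE
  )
}

#' Extract the sample range of a trial period
#'
#' @param epoch A `trial_epoch`.
#' @param period One of `"rest"`, `"reference"`, `"mi"`, `"fes_init"`,
#'   `"feedback"`.
#' @return The channel x samples submatrix covering the period.
#' @export
period_segment <- function(epoch, period) {
  pb <- epoch$period_bounds
  row <- pb[pb$period == period, ]
  if (nrow(row) != 1) stop("period_segment: unknown period ", period)
  fs <- epoch$sampling_rate
  idx <- seq.int(floor(row$start * fs) + 1, floor(row$end * fs))
  epoch$signal[, idx, drop = FALSE]
}
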