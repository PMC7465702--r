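# Filtering primitives: Hamming windowed-sinc FIR band-pass (applied
# zero-phase via centered convolution) and a biquad IIR notch (applied
# zero-phase forward-backward). No external DSP dependency.

# Linear-phase FIR band-pass taps (Hamming window). lo = 0 gives low-pass.
fir_bandpass_taps <- function(fs, lo, hi, n_taps) {
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1 # odd length, exact center
  m <- (n_taps - 1) / 2
  k <- seq(-m, m)
  sinc <- function(fc) {
    x <- 2 * fc / fs
    ifelse(k == 0, x, sin(pi * x * k) / (pi * k))
  }
  h <- sinc(hi) - if (lo > 0) sinc(lo) else 0
  w <- 0.54 + 0.46 * cos(pi * k / m) # Hamming
  h * w
}

# Zero-phase FIR filtering of each row of x via FFT convolution with
# reflection padding. h must be odd-length symmetric.
apply_fir <- function(x, h) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  n <- ncol(x)
  m <- (length(h) - 1) / 2
  pad <- min(m, n - 1)
  nfft <- stats::nextn(n + 2 * pad + length(h))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  out <- x
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    xp <- c(rev(xi[seq_len(pad) + 1]), xi, rev(xi[n - seq_len(pad)]))
    X <- stats::fft(c(xp, numeric(nfft - length(xp))))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    out[i, ] <- y[pad + m + seq_len(n)]
  }
  out
}

# Biquad IIR notch (RBJ cookbook), returns list(b, a) with a[1] = 1.
notch_coefficients <- function(fs, f0, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Single-direction IIR via difference equation.
iir_once <- function(x, b, a) {
  z <- stats::filter(c(numeric(length(b) - 1), x), b, method = "convolution",
                     sides = 1)
  z <- z[-seq_len(length(b) - 1)]
  as.numeric(stats::filter(z, -a[-1], method = "recursive"))
}

# Zero-phase (forward-backward) IIR filtering of each row of x, with
# reflection padding to suppress edge transients.
apply_iir_filtfilt <- function(x, b, a) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  n <- ncol(x)
  pad <- min(3 * 100, n - 1)
  out <- x
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    xp <- c(2 * xi[1] - rev(xi[seq_len(pad) + 1]), xi,
            2 * xi[n] - rev(xi[n - seq_len(pad)]))
    y <- iir_once(xp, b, a)
    y <- rev(iir_once(rev(y), b, a))
    out[i, ] <- y[pad + seq_len(n)]
  }
  out
}
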