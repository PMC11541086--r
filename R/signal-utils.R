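# FFT-based signal primitives shared by the spectral, pac and evoked modules.
# All filtering here is zero-phase by construction (frequency-domain masks),
# which avoids the phase distortion that would bias phase-amplitude coupling.

#' Analytic signal via the Hilbert transform
#'
#' @param x numeric vector.
#' @return complex vector of the same length; `Mod()` is the amplitude
#'   envelope and `Arg()` the instantaneous phase (0 at a cosine peak).
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain filter with raised-cosine (soft) band edges. Zero-phase by
#' construction; the transition band on each side is `transition` times the
#' edge frequency (at least 0.5 Hz).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param low,high band edges in Hz, `0 <= low < high <= fs/2`.
#' @param transition relative transition-band width (default 0.15).
#' @return filtered numeric vector.
#' @export
bandpass <- function(x, fs, low, high, transition = 0.15) {
  if (low < 0 || high <= low || high > fs / 2)
    stop("need 0 <= low < high <= fs/2")
  n <- length(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  tw_lo <- max(0.5, transition * low)
  tw_hi <- max(0.5, transition * high)
  ramp_up <- function(f, f0, tw) {          # 0 below f0-tw, 1 above f0
    ifelse(f >= f0, 1, ifelse(f <= f0 - tw, 0, 0.5 * (1 + cos(pi * (f0 - f) / tw))))
  }
  mask <- if (low <= 0) 1 else ramp_up(f, low, tw_lo)
  mask <- mask * (1 - ramp_up(f, high + tw_hi, tw_hi))
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Complex Morlet wavelet
#'
#' Gaussian-windowed complex exponential with `n_cycles` cycles
#' (`sigma_t = n_cycles / (2 pi f)`), truncated at +/- 3.5 sigma and
#' normalized to unit energy.
#'
#' @param freq center frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param n_cycles wavelet length in cycles (default 3).
#' @return complex vector of odd length (the wavelet kernel).
#' @export
morlet_wavelet <- function(freq, fs, n_cycles = 3) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- max(1L, ceiling(3.5 * sigma_t * fs))
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * freq * t)
  w / sqrt(sum(Mod(w)^2))
}

# centered FFT convolution of a real series with a complex kernel ("same"
# size); returns complex series
conv_same <- function(x, kern) {
  n <- length(x); m <- length(kern)
  nf <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, numeric(nf - n)))
  K <- stats::fft(c(kern, complex(real = numeric(nf - m))))
  full <- stats::fft(X * K, inverse = TRUE) / nf
  half <- (m - 1) / 2
  full[(half + 1):(half + n)]
}
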