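# Segment-averaged spectra, magnitude-squared coherence with its analytic
# confidence limit, Morlet-wavelet power, and band summaries.

#' Standardize a series to zero mean and unit SD
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return standardized vector.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("series must have length >= 2")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a zero-variance series")
  (x - mean(x)) / s
}

# taper matrix: L x K (K tapers averaged per segment); sine tapers are the
# closed-form multitaper family (Riedel & Sidorenko)
.tapers <- function(L, taper, n_tapers) {
  switch(taper,
    boxcar = matrix(1, L, 1),
    hann = matrix(0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1))), L, 1),
    multitaper = {
      k <- seq_len(n_tapers)
      outer(seq_len(L), k, function(n, k) sqrt(2 / (L + 1)) * sin(pi * k * n / (L + 1)))
    },
    stop("unknown taper: ", taper))
}

#' Segment-averaged auto- and cross-spectra
#'
#' The two series are standardized, divided into `M = floor(N / L)` disjoint
#' segments of length `L` (remainder samples dropped and recorded), tapered,
#' and per-segment Fourier auto-/cross-spectra are averaged.
#'
#' @param x,y numeric series of equal length `N >= L`.
#' @param L segment length in samples (>= 2).
#' @param fs sampling rate (Hz) used only for the frequency axis (default 1).
#' @param taper `"hann"` (default), `"boxcar"`, or `"multitaper"` (sine
#'   tapers).
#' @param n_tapers taper count for the multitaper option.
#' @param standardize_input zero-mean / unit-SD each series first (default
#'   `TRUE`).
#' @return object of class `spectrum_estimate` with one-sided `freqs`,
#'   `Sxx`, `Syy`, `Sxy` (complex), segment count `M`, segment length `L`,
#'   and `n_dropped` remainder samples.
#' @export
segment_spectra <- function(x, y = x, L, fs = 1, taper = c("hann", "boxcar", "multitaper"),
                            n_tapers = 5, standardize_input = TRUE) {
  taper <- match.arg(taper)
  N <- length(x)
  if (length(y) != N) stop("x and y must have equal length")
  if (L < 2) stop("segment length L must be >= 2")
  if (N < L) stop(sprintf("series length %d is shorter than segment length %d", N, L))
  if (standardize_input) { x <- standardize(x); y <- standardize(y) }
  M <- N %/% L
  n_dropped <- N - M * L
  W <- .tapers(L, taper, n_tapers)
  U <- colSums(W^2)                           # taper power normalization
  nf <- L %/% 2 + 1
  Sxx <- Syy <- numeric(nf); Sxy <- complex(length.out = nf)
  for (m in seq_len(M)) {
    seg <- ((m - 1) * L + 1):(m * L)
    xs <- x[seg]; ys <- y[seg]
    for (k in seq_len(ncol(W))) {
      X <- stats::fft(xs * W[, k])[seq_len(nf)] / sqrt(U[k])
      Y <- if (identical(x, y) && standardize_input) X
           else stats::fft(ys * W[, k])[seq_len(nf)] / sqrt(U[k])
      Sxx <- Sxx + Mod(X)^2
      Syy <- Syy + Mod(Y)^2
      Sxy <- Sxy + X * Conj(Y)
    }
  }
  nk <- M * ncol(W)
  structure(list(freqs = (seq_len(nf) - 1) * fs / L,
                 Sxx = Sxx / nk, Syy = Syy / nk, Sxy = Sxy / nk,
                 M = M, L = L, fs = fs, taper = taper,
                 n_dropped = n_dropped),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d frequencies, M = %d segments of L = %d (%s taper, %d dropped)\n",
              length(x$freqs), x$M, x$L, x$taper, x$n_dropped))
  invisible(x)
}

#' Analytic confidence limit for segment-averaged coherence
#'
#' For coherence estimated from `M` averaged segments, values above
#' `1 - (1 - alpha)^(1 / (M - 1))` are significant at level `alpha`.
#'
#' @param M segment count (>= 2).
#' @param alpha confidence level in (0, 1); default 0.99.
#' @return the confidence limit, in `[0, 1]`.
#' @examples
#' coherence_confidence_limit(2, 0.99)   # 0.99
#' coherence_confidence_limit(11, 0.99)  # 1 - 0.01^0.1
#' @export
coherence_confidence_limit <- function(M, alpha = 0.99) {
  if (M < 2) stop("confidence limit undefined for M < 2 segments")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  1 - (1 - alpha)^(1 / (M - 1))
}

#' Magnitude-squared coherence with confidence limit
#'
#' `coh(f) = |Sxy|^2 / (Sxx * Syy)` on segment-averaged spectra, with the
#' analytic significance threshold of [coherence_confidence_limit()]
#' attached.
#'
#' @inheritParams segment_spectra
#' @param alpha confidence level for the limit (default 0.99).
#' @return object of class `coherence_result` with `freqs`, `coherence` in
#'   `[0, 1]`, `M`, `alpha`, `conf_limit`.
#' @export
coherence <- function(x, y, L, fs = 1, alpha = 0.99,
                      taper = c("hann", "boxcar", "multitaper"), n_tapers = 5) {
  taper <- match.arg(taper)
  sp <- segment_spectra(x, y, L, fs = fs, taper = taper, n_tapers = n_tapers)
  if (sp$M < 2) stop("confidence limit undefined for M < 2 segments; shorten L or lengthen the series")
  denom <- sp$Sxx * sp$Syy
  coh <- ifelse(denom > 0, Mod(sp$Sxy)^2 / denom, 0)
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(freqs = sp$freqs, coherence = coh, M = sp$M, L = sp$L,
                 alpha = alpha,
                 conf_limit = coherence_confidence_limit(sp$M, alpha),
                 taper = taper, fs = fs),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d frequencies, M = %d, conf limit (alpha = %g) = %.3f\n",
              length(x$freqs), x$M, x$alpha, x$conf_limit))
  invisible(x)
}

#' Morlet-wavelet power spectrum
#'
#' Convolves the series with complex Morlet wavelets (default three cycles)
#' at each center frequency and time-averages the magnitude of the transform
#' (`power_exponent = 1`, the literal "absolute value"; use 2 for squared
#' magnitude). An edge region of one wavelet half-length is excluded from the
#' average at each end.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param freqs center-frequency grid (Hz); default `1:100`.
#' @param n_cycles wavelet length in cycles (default 3).
#' @param power_exponent 1 (magnitude, default) or 2 (squared magnitude).
#' @return data.frame with columns `freq` and `power`.
#' @export
wavelet_power <- function(x, fs, freqs = 1:100, n_cycles = 3,
                          power_exponent = 1) {
  n <- length(x)
  out <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    kern <- morlet_wavelet(freqs[i], fs, n_cycles)
    half <- (length(kern) - 1) / 2
    if (n <= 2 * half + 1)
      stop(sprintf("series too short: need > %d samples for %g Hz at %g cycles",
                   2 * half + 1, freqs[i], n_cycles))
    tf <- conv_same(x, kern)
    keep <- (half + 1):(n - half)
    out[i] <- mean(Mod(tf[keep])^power_exponent)
  }
  data.frame(freq = freqs, power = out)
}

#' Frequency-band definitions by species profile
#'
#' Returns the band set for the requested profile. The profile is mandatory:
#' human theta is 4-8 Hz while mouse theta is 7-12 Hz, and the two must never
#' be mixed silently.
#'
#' @param profile `"human"` or `"mouse"` (no default).
#' @return named list of `c(low, high)` bands: `theta`, `gamma`,
#'   `low_gamma`, `high_gamma`.
#' @export
band_profile <- function(profile) {
  if (missing(profile)) stop("profile is mandatory: choose \"human\" or \"mouse\"")
  profile <- match.arg(profile, c("human", "mouse"))
  theta <- if (profile == "human") c(4, 8) else c(7, 12)
  list(theta = theta, gamma = c(30, 100),
       low_gamma = c(30, 70), high_gamma = c(70, 100))
}

#' Band summary of a spectrum
#'
#' Mean over in-band bins (band edges inclusive) plus the in-band peak.
#'
#' @param spectrum a `spectrum_estimate`, `coherence_result`, or a data.frame
#'   with columns `freq`/`power` (or a list with `freqs` and a value vector).
#' @param band `c(low, high)` in Hz, `low < high`.
#' @param what for `spectrum_estimate`/`coherence_result` inputs, which
#'   values to summarize (`"Sxx"`, `"Syy"`, or `"coherence"`).
#' @return object of class `band_summary`: `band`, `mean_value`,
#'   `peak_freq`, `peak_value`, `n_bins`.
#' @export
band_summary <- function(spectrum, band, what = NULL) {
  if (band[1] >= band[2]) stop("band must satisfy low < high")
  if (is.data.frame(spectrum)) {
    freqs <- spectrum$freq; vals <- spectrum$power
  } else if (inherits(spectrum, "coherence_result")) {
    freqs <- spectrum$freqs; vals <- spectrum$coherence
  } else if (inherits(spectrum, "spectrum_estimate")) {
    if (is.null(what)) what <- "Sxx"
    freqs <- spectrum$freqs; vals <- spectrum[[what]]
  } else stop("unsupported spectrum input")
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(sel)) stop("band contains no frequency bins after discretization")
  pk <- sel[which.max(vals[sel])]
  structure(list(band = band, mean_value = mean(vals[sel]),
                 peak_freq = freqs[pk], peak_value = vals[pk],
                 n_bins = length(sel)),
            class = "band_summary")
}

#' @export
print.band_summary <- function(x, ...) {
  cat(sprintf("<band_summary> %g-%g Hz: mean %.4g, peak %.4g at %.3g Hz (%d bins)\n",
              x$band[1], x$band[2], x$mean_value, x$peak_value, x$peak_freq,
              x$n_bins))
  invisible(x)
}

#' Write a spectrum or coherence result as tidy CSV
#'
#' @param x a `spectrum_estimate` or `coherence_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  df <- if (inherits(x, "coherence_result"))
    data.frame(frequency = x$freqs, coherence = x$coherence,
               conf_limit = x$conf_limit)
  else if (inherits(x, "spectrum_estimate"))
    data.frame(frequency = x$freqs, Sxx = x$Sxx, Syy = x$Syy,
               cross_re = Re(x$Sxy), cross_im = Im(x$Sxy))
  else if (is.data.frame(x)) x
  else stop("unsupported input")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
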