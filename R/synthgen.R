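# Synthetic-data generators. These state the ground truth that the analysis
# modules are tested against: a theta oscillation in one region whose phase
# modulates the gamma envelope of a second region (with a shared noise source
# controlling coherence), EEG built from a few quasi-stable topographies,
# stimulus-locked epochs with a known injected response, and two-group score
# samples that can be moment-matched exactly to printed means and SDs.

#' Specification of a coupled two-region oscillation pair
#'
#' Parameters for [gen_coupled_pair()]. Region A carries a theta oscillation
#' at `theta_freq`; region B carries gamma at `gamma_freq` whose envelope is
#' `gamma_amp * (1 + d cos(phi_theta))`, so the phase-binned modulation index
#' has closed form `m = 2 d / (1 + d)`. A fraction `w` of the additive noise
#' in each region is a shared source, which controls inter-region coherence;
#' `w_theta` / `w_gamma` optionally override the mix inside the theta and
#' gamma bands so band-specific coherence contrasts can be planted.
#'
#' @param theta_freq,gamma_freq oscillation frequencies (Hz).
#' @param theta_amp,gamma_amp oscillation amplitudes (signal units).
#' @param d coupling depth in `[0, 1]`.
#' @param w shared-source fraction in `[0, 1]` (coherence mix).
#' @param noise_sd additive white-noise SD (signal units).
#' @param fs sampling rate (Hz), must exceed `2 * gamma_freq`.
#' @param duration length in seconds; `duration * fs` must be a positive
#'   integer.
#' @param seed integer RNG seed.
#' @param w_theta,w_gamma optional band-specific shared-source fractions
#'   (default `w`).
#' @param theta_band,gamma_band bands (Hz) used for the band-specific mixes.
#' @return A validated list of class `coupling_spec`.
#' @export
coupling_spec <- function(theta_freq = 5, gamma_freq = 60, theta_amp = 1,
                          gamma_amp = 0.5, d = 0.5, w = 0.3, noise_sd = 0.2,
                          fs = 1000, duration = 60, seed = 1,
                          w_theta = NULL, w_gamma = NULL,
                          theta_band = NULL, gamma_band = c(30, 100)) {
  if (is.null(w_theta)) w_theta <- w
  if (is.null(w_gamma)) w_gamma <- w
  if (is.null(theta_band)) theta_band <- c(max(0.5, theta_freq - 2), theta_freq + 2)
  s <- list(theta_freq = theta_freq, gamma_freq = gamma_freq,
            theta_amp = theta_amp, gamma_amp = gamma_amp, d = d, w = w,
            noise_sd = noise_sd, fs = fs, duration = duration, seed = seed,
            w_theta = w_theta, w_gamma = w_gamma,
            theta_band = theta_band, gamma_band = gamma_band)
  for (f in c("d", "w", "w_theta", "w_gamma"))
    if (s[[f]] < 0 || s[[f]] > 1)
      stop(sprintf("coupling_spec invariant violated: 0 <= %s <= 1", f))
  if (fs <= 2 * gamma_freq)
    stop("coupling_spec invariant violated: fs > 2 * gamma_freq")
  n <- duration * fs
  if (n <= 0 || abs(n - round(n)) > 1e-9)
    stop("coupling_spec invariant violated: duration * fs must be a positive integer")
  if (noise_sd < 0) stop("coupling_spec invariant violated: noise_sd >= 0")
  class(s) <- "coupling_spec"
  s
}

# split a white series into theta-band / gamma-band / remainder components
.band_split <- function(x, fs, theta_band, gamma_band) {
  th <- bandpass(x, fs, theta_band[1], theta_band[2])
  ga <- bandpass(x, fs, gamma_band[1], gamma_band[2])
  list(theta = th, gamma = ga, rest = x - th - ga)
}

#' Generate a coupled theta/gamma region pair
#'
#' See [coupling_spec()] for the generative model. The returned ground-truth
#' theta phase is the analytic phase of the noiseless theta component (exact
#' by construction), so it is independent of any estimator under test.
#'
#' @param spec a [coupling_spec()].
#' @return list with `region_A`, `region_B` (single-channel [recording()]s),
#'   the ground-truth `theta_phase`, and the `spec`.
#' @examples
#' pair <- gen_coupled_pair(coupling_spec(duration = 2, seed = 42))
#' pair$region_A
#' @export
gen_coupled_pair <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  n <- as.integer(round(spec$duration * spec$fs))
  t <- (seq_len(n) - 1) / spec$fs
  phase <- 2 * pi * spec$theta_freq * t
  theta <- spec$theta_amp * cos(phase)
  gamma <- spec$gamma_amp * (1 + spec$d * cos(phase)) * cos(2 * pi * spec$gamma_freq * t)
  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    shared <- rnorm(n); pA <- rnorm(n); pB <- rnorm(n)
    if (spec$w_theta == spec$w && spec$w_gamma == spec$w) {
      mix <- function(p) sqrt(spec$w) * shared + sqrt(1 - spec$w) * p
      eA <- mix(pA); eB <- mix(pB)
    } else {
      cs <- .band_split(shared, spec$fs, spec$theta_band, spec$gamma_band)
      As <- .band_split(pA, spec$fs, spec$theta_band, spec$gamma_band)
      Bs <- .band_split(pB, spec$fs, spec$theta_band, spec$gamma_band)
      wts <- c(theta = spec$w_theta, gamma = spec$w_gamma, rest = spec$w)
      mix <- function(p) Reduce(`+`, lapply(names(wts), function(b)
        sqrt(wts[[b]]) * cs[[b]] + sqrt(1 - wts[[b]]) * p[[b]]))
      eA <- mix(As); eB <- mix(Bs)
    }
    eA <- spec$noise_sd * eA; eB <- spec$noise_sd * eB
  } else {
    eA <- eB <- numeric(n)
  }
  list(region_A = recording(theta + eA, spec$fs, "region_A", units = "a.u."),
       region_B = recording(gamma + eB, spec$fs, "region_B", units = "a.u."),
       theta_phase = ((phase + pi) %% (2 * pi)) - pi,
       spec = spec)
}

#' Specification of synthetic microstate EEG
#'
#' @param topographies channels x k numeric matrix; each column must have
#'   zero mean and unit norm across channels and columns must be pairwise
#'   non-collinear.
#' @param mean_dwell mean state dwell time (ms).
#' @param fs sampling rate (Hz).
#' @param duration length (s).
#' @param snr amplitude signal-to-noise ratio (RMS signal / RMS noise); `Inf`
#'   for noiseless data.
#' @param seed integer RNG seed.
#' @return A validated list of class `microstate_spec`.
#' @export
microstate_spec <- function(topographies, mean_dwell = 100, fs = 250,
                            duration = 60, snr = 5, seed = 1) {
  topographies <- as.matrix(topographies)
  k <- ncol(topographies)
  if (k < 1) stop("need k >= 1 topographies")
  cm <- colMeans(topographies)
  nm <- sqrt(colSums(topographies^2))
  if (any(abs(cm) > 1e-8) || any(abs(nm - 1) > 1e-8))
    stop("microstate_spec invariant violated: topographies must be zero-mean, unit-norm")
  if (k > 1) {
    cc <- abs(crossprod(topographies))
    diag(cc) <- 0
    if (any(cc > 0.999)) stop("topographies must be pairwise non-collinear")
  }
  if (mean_dwell <= 0) stop("microstate_spec invariant violated: mean_dwell > 0")
  structure(list(topographies = topographies, n_channels = nrow(topographies),
                 k = k, mean_dwell = mean_dwell, fs = fs, duration = duration,
                 snr = snr, seed = seed),
            class = "microstate_spec")
}

#' Random zero-mean unit-norm topography set
#'
#' Convenience constructor of `k` orthonormalized random channel maps for
#' [microstate_spec()].
#'
#' @param n_channels channel count.
#' @param k number of maps.
#' @param seed RNG seed.
#' @return channels x k matrix of zero-mean, unit-norm, mutually orthogonal
#'   maps.
#' @export
random_topographies <- function(n_channels, k = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_channels * k), n_channels)
  m <- sweep(m, 2, colMeans(m))               # zero mean across channels
  q <- qr.Q(qr(m))                            # orthonormalize
  q <- sweep(q, 2, colMeans(q))               # re-center (stays ~orthogonal)
  sweep(q, 2, sqrt(colSums(q^2)), "/")
}

#' Generate EEG from quasi-stable topographies
#'
#' The channel vector at sample t is `a_t * s_r * topography[state_t]` plus
#' white noise scaled to the requested SNR. Dwell times are geometric with
#' the stated mean (memoryless switching); the per-sample amplitude `a_t`
#' fluctuates around a typical strength without vanishing
#' (`|N(1, 0.3^2)|`), and the polarity `s_r` is constant within an instance
#' and random across instances (the back-fitting step is polarity-invariant).
#'
#' @param spec a [microstate_spec()].
#' @return list with `eeg` (a [recording()]) and the ground-truth integer
#'   `states` sequence.
#' @export
gen_microstate_eeg <- function(spec) {
  stopifnot(inherits(spec, "microstate_spec"))
  n <- as.integer(round(spec$duration * spec$fs))
  mean_samp <- spec$mean_dwell / 1000 * spec$fs
  if (mean_samp < 1) stop("mean_dwell shorter than one sample")
  set.seed(spec$seed)
  states <- integer(n); signs <- numeric(n)
  pos <- 1L; cur <- sample.int(spec$k, 1)
  while (pos <= n) {
    run <- 1L + stats::rgeom(1, 1 / mean_samp)
    idx <- pos:min(n, pos + run - 1L)
    states[idx] <- cur
    signs[idx] <- sample(c(-1, 1), 1)
    pos <- pos + run
    cur <- if (spec$k == 1) 1L else sample(setdiff(seq_len(spec$k), cur), 1)
  }
  amp <- abs(rnorm(n, 1, 0.3)) * signs
  sig <- spec$topographies[, states, drop = FALSE] *
    rep(amp, each = spec$n_channels)
  if (is.finite(spec$snr)) {
    # E[frame power] = E[a^2] * ||topo||^2 / n_ch = E[a^2] / n_ch
    sig_rms <- sqrt(mean(amp^2) / spec$n_channels)
    noise <- matrix(rnorm(length(sig), 0, sig_rms / spec$snr), nrow(sig))
    sig <- sig + noise
  }
  list(eeg = recording(sig, spec$fs,
                       paste0("E", seq_len(spec$n_channels)), units = "uV"),
       states = states)
}

#' Specification of two-group score samples
#'
#' @param mean1,sd1,n1 first-group mean, SD and size.
#' @param mean2,sd2,n2 second-group mean, SD and size.
#' @param moment_match if `TRUE`, each sample is affinely rescaled so its
#'   sample mean and SD equal the requested values exactly.
#' @param seed integer RNG seed.
#' @return A validated list of class `group_spec`.
#' @export
group_spec <- function(mean1, sd1, n1, mean2, sd2, n2,
                       moment_match = TRUE, seed = 1) {
  if (sd1 <= 0 || sd2 <= 0) stop("group_spec invariant violated: sd1, sd2 > 0")
  if (n1 < 2 || n2 < 2) stop("group_spec invariant violated: n1, n2 >= 2")
  structure(list(mean1 = mean1, sd1 = sd1, n1 = n1, mean2 = mean2, sd2 = sd2,
                 n2 = n2, moment_match = moment_match, seed = seed),
            class = "group_spec")
}

#' Generate two-group Gaussian score samples
#'
#' @param spec a [group_spec()].
#' @return list with numeric vectors `group1` and `group2`. With
#'   `moment_match = TRUE` the sample mean and (n-1) SD of each group equal
#'   the requested moments to floating precision.
#' @examples
#' g <- gen_group_scores(group_spec(273.7, 35.1, 25, 266.1, 32.3, 25))
#' c(mean(g$group1), sd(g$group1))
#' @export
gen_group_scores <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  set.seed(spec$seed)
  draw <- function(n, m, s) {
    x <- rnorm(n, m, s)
    if (spec$moment_match) x <- (x - mean(x)) / sd(x) * s + m
    x
  }
  list(group1 = draw(spec$n1, spec$mean1, spec$sd1),
       group2 = draw(spec$n2, spec$mean2, spec$sd2))
}

#' Generate stimulus-locked epochs with a known injected response
#'
#' Each epoch contains the same deterministic post-stimulus response (a
#' decaying oscillation distributed over channels by `channel_weights`) plus
#' independent white noise. The time axis places t = 0 at the stimulus.
#'
#' @param n_epochs epoch count.
#' @param pre,post seconds before / after the stimulus; must cover the
#'   standard analysis window (`pre >= 0.25`, `post >= 2`).
#' @param fs sampling rate (Hz).
#' @param response_spec list with elements `amp` (peak amplitude), `freq`
#'   (Hz), `decay` (s, exponential time constant), `onset` (s, default 0)
#'   and optional `channel_weights`.
#' @param seed RNG seed.
#' @param n_channels channel count (default 16).
#' @param noise_sd additive white-noise SD.
#' @param channel_labels optional labels (defaults to the frontal 10-10 set
#'   when `n_channels == 16`).
#' @return an [epochs()] object; the noiseless evoked response is attached as
#'   attribute `"truth"`.
#' @export
gen_evoked_epochs <- function(n_epochs, pre, post, fs,
                              response_spec = list(amp = 1, freq = 10, decay = 0.3),
                              seed = 1, n_channels = 16, noise_sd = 0.1,
                              channel_labels = NULL) {
  if (pre < 0.25 || post < 2)
    stop("epoch window (-pre, post) must cover the analysis window (-0.25, 2) s")
  rs <- utils::modifyList(list(amp = 1, freq = 10, decay = 0.3, onset = 0),
                          response_spec)
  n_pre <- round(pre * fs); n_post <- round(post * fs)
  time <- (-n_pre:n_post) / fs
  resp <- ifelse(time >= rs$onset,
                 rs$amp * exp(-(time - rs$onset) / rs$decay) *
                   sin(2 * pi * rs$freq * (time - rs$onset)),
                 0)
  w <- rs$channel_weights
  if (is.null(w)) w <- seq(1, 0.5, length.out = n_channels)
  truth <- outer(w, resp)
  set.seed(seed)
  arr <- array(rnorm(n_channels * length(time) * n_epochs, 0, noise_sd),
               dim = c(n_channels, length(time), n_epochs))
  arr <- arr + as.vector(truth)               # recycles over epochs
  if (is.null(channel_labels))
    channel_labels <- if (n_channels == 16) frontal_electrodes_1010()
                      else paste0("ch", seq_len(n_channels))
  ep <- epochs(arr, fs, t0_index = n_pre + 1, channel_labels = channel_labels)
  attr(ep, "truth") <- truth
  ep
}

#' Default frontal electrode subset (10-10 system)
#'
#' Sixteen frontal labels from the extended 10-10 montage used as the default
#' pooling set for global mean field power. This is configuration, not a
#' claim about any particular study's montage.
#'
#' @return character vector of 16 labels.
#' @export
frontal_electrodes_1010 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6")
}

#' Write group scores / label sequences as plain text
#'
#' `write_group_scores` writes a two-column CSV (`group,value`);
#' `write_labels` writes a one-column text file.
#'
#' @param group1,group2 numeric score vectors.
#' @param path output file.
#' @param labels vector of labels.
#' @return the path, invisibly.
#' @export
write_group_scores <- function(group1, group2, path) {
  df <- data.frame(group = rep(c("group1", "group2"),
                               c(length(group1), length(group2))),
                   value = c(group1, group2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_group_scores
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}
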