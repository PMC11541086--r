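# brute-force DFT periodogram-average oracle: direct complex-exponential
# sums per disjoint segment, no FFT, no taper
oracle_segment_spectra <- function(x, y, L) {
  x <- (x - mean(x)) / sd(x); y <- (y - mean(y)) / sd(y)
  M <- length(x) %/% L
  nf <- L %/% 2 + 1
  Sxx <- Syy <- numeric(nf); Sxy <- complex(length.out = nf)
  for (m in seq_len(M)) {
    seg <- ((m - 1) * L + 1):(m * L)
    for (k in seq_len(nf)) {
      e <- exp(-2i * pi * (k - 1) * (0:(L - 1)) / L)
      X <- sum(x[seg] * e); Y <- sum(y[seg] * e)
      Sxx[k] <- Sxx[k] + Mod(X)^2 / L
      Syy[k] <- Syy[k] + Mod(Y)^2 / L
      Sxy[k] <- Sxy[k] + X * Conj(Y) / L
    }
  }
  list(Sxx = Sxx / M, Syy = Syy / M, Sxy = Sxy / M, M = M)
}

test_that("standardize gives mean 0, SD 1, is idempotent, and rejects constants", {
  set.seed(1)
  x <- rnorm(100, 5, 3)
  s <- standardize(x)
  expect_lt(abs(mean(s)), 1e-12)
  expect_lt(abs(sd(s) - 1), 1e-12)
  expect_equal(standardize(s), s, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "zero-variance")
  expect_error(standardize(3), "length")
})

test_that("segment_spectra matches a direct-DFT periodogram-average oracle", {
  set.seed(2)
  x <- rnorm(1600); y <- rnorm(1600)
  est <- segment_spectra(x, y, L = 32, taper = "boxcar")     # M = 50
  orc <- oracle_segment_spectra(x, y, 32)
  expect_equal(est$M, 50)
  expect_equal(est$Sxx, orc$Sxx, tolerance = 1e-10)
  expect_equal(est$Syy, orc$Syy, tolerance = 1e-10)
  expect_equal(est$Sxy, orc$Sxy, tolerance = 1e-10)
  # white noise: flat within sampling error
  expect_lt(max(abs(est$Sxx[-c(1, length(est$Sxx))] - mean(est$Sxx[-c(1, 17)]))),
            6 * mean(est$Sxx) / sqrt(50))
})

test_that("segment_spectra: x = y gives Sxy = Sxx; sinusoid concentrates at f0", {
  set.seed(3)
  x <- rnorm(512)
  est <- segment_spectra(x, x, L = 128)
  expect_equal(Re(est$Sxy), est$Sxx, tolerance = 1e-12)
  expect_equal(Im(est$Sxy), rep(0, length(est$Sxx)), tolerance = 1e-12)
  t <- (0:799) / 100
  s <- sin(2 * pi * 10 * t)                # L = 100 is a whole period count
  e2 <- segment_spectra(s, s, L = 100, fs = 100, taper = "boxcar")
  pk <- which.max(e2$Sxx)
  expect_equal(e2$freqs[pk], 10)
  expect_gt(e2$Sxx[pk], 100 * max(e2$Sxx[-pk]))
  expect_error(segment_spectra(x, x, L = 1024), "shorter")
  expect_error(segment_spectra(x, rnorm(100), L = 32), "equal length")
})

test_that("M = 1 segment-averaged spectrum equals the plain periodogram", {
  set.seed(4)
  x <- rnorm(256)
  est <- segment_spectra(x, x, L = 256, taper = "boxcar")
  xs <- (x - mean(x)) / sd(x)
  pg <- Mod(stats::fft(xs)[1:129])^2 / 256
  expect_equal(est$M, 1)
  expect_equal(est$Sxx, pg, tolerance = 1e-10)
})

test_that("confidence limit formula is exact and monotone", {
  expect_identical(coherence_confidence_limit(2, 0.99), 0.99)
  expect_equal(coherence_confidence_limit(11, 0.99), 1 - 0.01^0.1,
               tolerance = 1e-15)
  grid <- 2:60
  lims <- vapply(grid, coherence_confidence_limit, numeric(1))
  expect_true(all(diff(lims) < 0))
  expect_lt(coherence_confidence_limit(10000), 0.001)
  expect_error(coherence_confidence_limit(1), "M < 2")
  expect_error(coherence_confidence_limit(10, 1.2), "alpha")
})

test_that("coherence: identity, bounds, and affine invariance", {
  set.seed(5)
  x <- rnorm(4000)
  ch <- coherence(x, x, L = 400)
  expect_equal(ch$coherence, rep(1, length(ch$coherence)), tolerance = 1e-9)
  y <- rnorm(4000)
  ch2 <- coherence(x, y, L = 400)
  expect_true(all(ch2$coherence >= -1e-9 & ch2$coherence <= 1 + 1e-9))
  ch3 <- coherence(3.2 * x - 7, -0.5 * y + 11, L = 400)
  expect_equal(ch3$coherence, ch2$coherence, tolerance = 1e-9)
  expect_error(coherence(x, y, L = 4000), "M < 2")
})

test_that("coherence under additive independent noise approaches s/(1+s)", {
  set.seed(6)
  n <- 30000
  x <- rnorm(n)
  y <- x + rnorm(n)                        # per-frequency SNR s = 1
  ch <- coherence(x, y, L = 1000, fs = 1000)
  expect_lt(abs(mean(ch$coherence[-1]) - 0.5), 0.03)
})

test_that("multitaper and boxcar tapers give compatible coherence", {
  set.seed(7)
  x <- rnorm(6000); y <- x + rnorm(6000)
  for (tp in c("boxcar", "multitaper")) {
    ch <- coherence(x, y, L = 500, taper = tp)
    expect_lt(abs(mean(ch$coherence[-1]) - 0.5), 0.08)
  }
})

test_that("wavelet power localizes sinusoids and is zero on silence", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  wp <- wavelet_power(sin(2 * pi * 10 * t), fs, freqs = 1:60)
  expect_equal(wp$freq[which.max(wp$power)], 10)
  wp2 <- wavelet_power(sin(2 * pi * 10 * t) + sin(2 * pi * 40 * t), fs,
                       freqs = 1:60)
  # three-cycle wavelets are spectrally broad (sigma_f = f/3) and the
  # unit-energy normalization tilts gain slightly toward lower frequencies,
  # so the high-frequency local maximum can sit a couple of bins low
  loc_max <- wp2$freq[which(diff(sign(diff(wp2$power))) == -2) + 1]
  expect_true(any(abs(loc_max - 10) <= 1))
  expect_true(any(abs(loc_max - 40) <= 2))
  wp3 <- wavelet_power(numeric(5 * fs), fs, freqs = c(5, 20, 80))
  expect_equal(wp3$power, c(0, 0, 0))
  expect_error(wavelet_power(rnorm(200), fs, freqs = 1), "too short")
})

test_that("band_summary matches a brute-force loop and validates bands", {
  set.seed(8)
  sp <- data.frame(freq = 1:100, power = runif(100))
  bs <- band_summary(sp, c(30, 70))
  # brute-force loop oracle
  acc <- c(); pk <- -Inf; pkf <- NA
  for (i in seq_len(nrow(sp))) {
    if (sp$freq[i] >= 30 && sp$freq[i] <= 70) {
      acc <- c(acc, sp$power[i])
      if (sp$power[i] > pk) { pk <- sp$power[i]; pkf <- sp$freq[i] }
    }
  }
  expect_equal(bs$mean_value, mean(acc))
  expect_equal(bs$peak_value, pk)
  expect_equal(bs$peak_freq, pkf)
  expect_true(bs$peak_freq >= 30 && bs$peak_freq <= 70)
  flat <- data.frame(freq = 1:50, power = rep(3.5, 50))
  expect_equal(band_summary(flat, c(10, 20))$mean_value, 3.5)
  expect_error(band_summary(sp, c(20, 10)), "low < high")
  expect_error(band_summary(sp, c(200.2, 200.4)), "no frequency bins")
})

test_that("band profiles are species-specific and profile choice is mandatory", {
  expect_error(band_profile(), "mandatory")
  expect_equal(band_profile("human")$theta, c(4, 8))
  expect_equal(band_profile("mouse")$theta, c(7, 12))
  expect_equal(band_profile("mouse")$low_gamma, c(30, 70))
  expect_equal(band_profile("human")$high_gamma, c(70, 100))
})
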