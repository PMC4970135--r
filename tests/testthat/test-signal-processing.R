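make_tone <- function(freq, fs = 10e6, n = 1024, amp = 1, phase = 0) {
  waveform(amp * sin(2 * pi * freq * (0:(n - 1)) / fs + phase), 1 / fs)
}

test_that("amplitude spectrum concentrates a bin-centred tone in one bin", {
  fs <- 10e6; n <- 1024
  k <- 64 # bin index -> frequency k * fs / n
  w <- make_tone(k * fs / n, fs, n)
  s <- amplitude_spectrum(w)
  mags <- Mod(s$values)
  expect_equal(which.max(mags), k + 1L)
  expect_gt(mags[k + 1L], 100 * max(mags[-(k + 1L)]))
})

test_that("amplitude spectrum satisfies Parseval's identity", {
  set.seed(5)
  x <- rnorm(256)
  w <- waveform(x, 1e-7)
  full <- Mod(stats::fft(x))^2
  expect_equal(sum(x^2), sum(full) / 256, tolerance = 1e-12)
  # one-sided spectrum carries the non-negative half of the same DFT
  s <- amplitude_spectrum(w)
  expect_equal(s$values, stats::fft(x)[1:129], tolerance = 1e-12)
})

test_that("all-zero waveform yields an all-zero spectrum flagged undefined", {
  s <- amplitude_spectrum(waveform(rep(0, 64), 1e-7))
  expect_true(all(s$values == 0))
  expect_true(all(magnitude_db(s) == -Inf)) # undefined in dB
  expect_error(waveform(rnorm(8), 1e-7), "16")
})

test_that("sensitivity is the spectral ratio in dB", {
  fs <- 10e6; n <- 1024
  tx <- make_tone(fs / 16, fs, n)
  # ratio 1 -> 0 dB at every defined bin
  s0 <- sensitivity_db(tx, tx)
  expect_equal(s0$sensitivity_db[!is.na(s0$sensitivity_db)],
               rep(0, sum(!is.na(s0$sensitivity_db))), tolerance = 1e-9)
  # scaled copies: 0.1 -> -20 dB; 10^(-29/20) -> -29 dB (a typical printed
  # peak sensitivity for an air-coupled pair)
  for (case in list(c(0.1, -20), c(10^(-29 / 20), -29))) {
    rx <- waveform(tx$samples * case[1], tx$sample_interval)
    s <- sensitivity_db(tx, rx)
    k <- which.max(Mod(amplitude_spectrum(tx)$values))
    expect_equal(s$sensitivity_db[k], case[2], tolerance = 1e-9)
  }
})

test_that("substitution normalisation recovers a known transmission exactly", {
  vitis <- table3_vitis()
  f <- seq(3e5, 9e5, by = 2e3)
  T_true <- layer_transmission(vitis, frequencies = f)
  ref <- complex_spectrum(f, complex(modulus = runif(length(f), 0.5, 2),
                                     argument = runif(length(f), -pi, pi)))
  with_leaf <- complex_spectrum(f, T_true$values * ref$values)
  got <- measured_transmission(with_leaf, ref)
  expect_equal(got$values, T_true$values, tolerance = 1e-12)
  # self-normalisation gives unity
  self <- measured_transmission(ref, ref)
  expect_equal(self$values, rep(1 + 0i, length(f)), tolerance = 1e-12)
  expect_equal(magnitude_db(self), rep(0, length(f)), tolerance = 1e-9)
  # grid mismatch rejected
  ref2 <- complex_spectrum(f + 1, ref$values)
  expect_error(measured_transmission(with_leaf, ref2), "grids")
})

test_that("noisy substitution magnitude error matches the noise model", {
  # with-leaf = T * ref + complex noise of sd sigma per bin: the magnitude
  # error of the ratio has RMS ~ sigma / |ref| for small noise
  set.seed(77)
  f <- seq(3e5, 5e5, by = 5e3)
  n <- length(f)
  ref <- complex_spectrum(f, rep(2 + 0i, n))
  T_true <- rep(0.1 + 0i, n)
  snr_db <- 40
  sigma <- Mod(T_true[1]) * 2 * 10^(-snr_db / 20) # noise sd on the raw signal
  errs <- replicate(300, {
    noise <- complex(real = rnorm(n, sd = sigma / sqrt(2)),
                     imaginary = rnorm(n, sd = sigma / sqrt(2)))
    got <- measured_transmission(complex_spectrum(f, T_true * 2 + noise), ref)
    sqrt(mean((Mod(got$values) - 0.1)^2))
  })
  # E[rms magnitude error] ~ sigma/|ref| * sqrt(1/2) for circular noise
  expected <- sigma / 2 / sqrt(2)
  expect_lt(abs(mean(errs) - expected) / expected, 0.1)
})

test_that("resonance features locate a constructed symmetric peak", {
  f <- seq(2e5, 5e5, by = 1e3)
  mag_db <- -40 - 20 * ((f - 3.5e5) / 5e4)^2 # parabola peaked at 350 kHz
  s <- complex_spectrum(f, 10^(mag_db / 20) + 0i)
  ft <- extract_resonance_features(s)
  expect_equal(ft$fres, 3.5e5, tolerance = 1e-6)
  expect_equal(ft$band_hi - 3.5e5, 3.5e5 - ft$band_lo, tolerance = 1e-3)
  expect_equal(ft$peak_magnitude_db, -40, tolerance = 1e-6)
  # -6 dB crossings of the parabola at +/- 5e4*sqrt(6/20)
  half <- 5e4 * sqrt(6 / 20)
  expect_equal(ft$band_hi, 3.5e5 + half, tolerance = 1e-3)
})

test_that("feature extraction agrees with a fine-grid brute-force scan", {
  coffea <- table3_coffea()
  s <- layer_transmission(coffea, frequencies = seq(1.5e5, 6e5, by = 1e3))
  ft <- extract_resonance_features(s)
  f_oracle <- oracle_peak_frequency(coffea, 2.5e5, 3.5e5)
  expect_lt(abs(ft$fres - f_oracle), 1e3)
})

test_that("monotone spectra are rejected as having no resonance", {
  f <- seq(2e5, 5e5, by = 1e3)
  s <- complex_spectrum(f, seq(1, 0.01, length.out = length(f)) + 0i)
  expect_error(extract_resonance_features(s), class = "ncrus_no_resonance")
})

test_that("features are level-invariant except the peak magnitude", {
  vitis <- table3_vitis()
  s <- layer_transmission(vitis, frequencies = seq(3e5, 1e6, by = 1e3))
  ft <- extract_resonance_features(s)
  shifted <- complex_spectrum(s$frequencies, s$values * 10^(12 / 20))
  ft2 <- extract_resonance_features(shifted)
  expect_equal(ft2$fres, ft$fres, tolerance = 1e-12)
  expect_equal(ft2$band_lo, ft$band_lo, tolerance = 1e-9)
  expect_equal(ft2$band_hi, ft$band_hi, tolerance = 1e-9)
  expect_equal(ft2$relative_bandwidth, ft$relative_bandwidth, tolerance = 1e-9)
  expect_equal(ft2$peak_magnitude_db, ft$peak_magnitude_db + 12,
               tolerance = 1e-9)
})

test_that("phase unwrapping matches the cumulative-difference oracle", {
  set.seed(13)
  for (i in 1:10) {
    true_phase <- cumsum(runif(200, -1, 1))
    wrapped <- Arg(exp(1i * true_phase))
    got <- unwrap_phase(wrapped)
    want <- oracle_unwrap(wrapped)
    expect_equal(got, want, tolerance = 1e-12)
    # and the reconstruction differs from the truth by a global 2 pi multiple
    expect_equal((got - true_phase) / (2 * pi),
                 rep(round((got[1] - true_phase[1]) / (2 * pi)), 200),
                 tolerance = 1e-9)
  }
})

test_that("pulse duration measures envelope width", {
  fs <- 20e6
  t <- (0:4095) / fs
  # rectangular burst of 20 us
  env_on <- t >= 10e-6 & t < 30e-6
  burst <- waveform(ifelse(env_on, sin(2 * pi * 1e6 * t), 0), 1 / fs)
  expect_equal(pulse_duration(burst, -20), 20e-6, tolerance = 0.05)
  expect_equal(pulse_duration(burst, -40), 20e-6, tolerance = 0.05)
  # Gaussian-windowed tone: at -20 dB the width is 2*sigma*sqrt(2 ln 10)
  sigma <- 3e-6
  gaus <- waveform(exp(-(t - 100e-6)^2 / (2 * sigma^2)) *
                     sin(2 * pi * 1e6 * t), 1 / fs)
  want <- 2 * sigma * sqrt(2 * log(10))
  expect_equal(pulse_duration(gaus, -20), want, tolerance = 0.02)
  # amplitude scaling leaves duration unchanged
  gaus2 <- waveform(5 * gaus$samples, 1 / fs)
  expect_equal(pulse_duration(gaus2, -20), pulse_duration(gaus, -20),
               tolerance = 1e-9)
  expect_error(pulse_duration(waveform(rep(0, 64), 1 / fs)), "peak")
})
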