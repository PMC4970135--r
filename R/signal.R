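#' Time-domain waveform
#'
#' A uniformly sampled voltage trace from the transmit or receive transducer.
#'
#' @param samples Numeric vector of at least 16 samples.
#' @param sample_interval Sampling interval, s.
#' @param label Optional character label (`"transmit"`, `"receive"`,
#'   `"reference"`, ...).
#' @return Object of class `waveform`.
#' @export
waveform <- function(samples, sample_interval, label = NULL) {
  stopifnot(is.numeric(samples), is.numeric(sample_interval),
            length(sample_interval) == 1L, sample_interval > 0)
  if (length(samples) < 16L)
    stop("waveform needs at least 16 samples, got ", length(samples))
  structure(list(samples = as.numeric(samples),
                 sample_interval = sample_interval, label = label),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform%s: %d samples at %.3g MHz (%.1f us)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$samples), 1e-6 / x$sample_interval,
              length(x$samples) * x$sample_interval * 1e6))
  invisible(x)
}

# taper window of length n; terse cosine family, enough for spectral estimation
taper_window <- function(n, window = c("none", "hann", "hamming")) {
  window <- match.arg(window)
  switch(window,
         none = rep(1, n),
         hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

#' One-sided amplitude spectrum of a waveform
#'
#' Discrete Fourier transform front-end: returns the complex spectrum on the
#' non-negative half of the DFT grid. The applied taper is recorded in the
#' spectrum metadata.
#'
#' @param wave A [waveform()].
#' @param window Taper applied before the transform; default `"none"`
#'   (appropriate for synthetic data; use a cosine taper for measured
#'   waveforms with truncation transients).
#' @return A [complex_spectrum()] covering 0..Nyquist; `meta$window` and
#'   `meta$n_samples` record provenance. The DC bin is included; bins with
#'   zero magnitude give `-Inf` in [magnitude_db()].
#' @export
amplitude_spectrum <- function(wave, window = c("none", "hann", "hamming")) {
  stopifnot(inherits(wave, "waveform"))
  window <- match.arg(window)
  x <- wave$samples * taper_window(length(wave$samples), window)
  n <- length(x)
  sp <- stats::fft(x)
  nh <- floor(n / 2) + 1L
  freq <- (seq_len(nh) - 1) / (n * wave$sample_interval)
  # complex_spectrum requires strictly increasing; DC included at f = 0
  complex_spectrum(freq, sp[seq_len(nh)],
                   meta = list(window = window, n_samples = n,
                               sample_interval = wave$sample_interval))
}

#' Through-transmission sensitivity in dB
#'
#' Per-frequency sensitivity of a transmit/receive pair,
#' \deqn{SNS(dB) = 20 \log_{10}\left(\frac{|FFT(V_{Rx})|}{|FFT(V_{Tx})|}\right),}
#' the standard figure of merit of an air-coupled transducer pair in
#' through transmission.
#'
#' @param tx Transmit-side [waveform()].
#' @param rx Receive-side [waveform()], same sampling and length.
#' @param window Taper, as in [amplitude_spectrum()].
#' @return Data frame with columns `frequency_hz` and `sensitivity_db`;
#'   bins where the transmit spectrum is zero are `NA` (undefined).
#' @export
sensitivity_db <- function(tx, rx, window = "none") {
  stopifnot(inherits(tx, "waveform"), inherits(rx, "waveform"))
  if (length(tx$samples) != length(rx$samples) ||
      tx$sample_interval != rx$sample_interval)
    stop("transmit and receive waveforms must share grid and length")
  stx <- amplitude_spectrum(tx, window)
  srx <- amplitude_spectrum(rx, window)
  mt <- Mod(stx$values)
  sns <- ifelse(mt > 0, 20 * log10(Mod(srx$values) / mt), NA_real_)
  data.frame(frequency_hz = stx$frequencies, sensitivity_db = sns)
}

#' Measured transmission by reference substitution
#'
#' Element-wise complex ratio of the spectrum received with the leaf in the
#' path to a reference spectrum of the bare air path. This is how insertion
#' spectra are measured in practice: the reference cancels the transducer and
#' electronics response.
#'
#' @param rx_with_leaf [complex_spectrum()] with the sample inserted.
#' @param rx_reference [complex_spectrum()] of the empty path, same grid.
#' @param noise_floor_db Reference bins with magnitude below this level
#'   (dB relative to the reference peak) are masked `NA`; default -100.
#' @return A [complex_spectrum()]; masked bins carry `NA` values and
#'   `meta$masked` gives their indices.
#' @export
measured_transmission <- function(rx_with_leaf, rx_reference,
                                  noise_floor_db = -100) {
  stopifnot(inherits(rx_with_leaf, "complex_spectrum"),
            inherits(rx_reference, "complex_spectrum"))
  if (!isTRUE(all.equal(rx_with_leaf$frequencies, rx_reference$frequencies)))
    stop("spectra are on different frequency grids")
  ref_mag <- Mod(rx_reference$values)
  floor_lin <- max(ref_mag) * 10^(noise_floor_db / 20)
  bad <- which(ref_mag <= floor_lin)
  vals <- rx_with_leaf$values / rx_reference$values
  vals[bad] <- NA_complex_
  complex_spectrum(rx_with_leaf$frequencies, vals,
                   meta = list(masked = bad, noise_floor_db = noise_floor_db))
}

# condition helper: absence of a usable resonance in the analysed band
stop_no_resonance <- function(msg = "no resonance in band") {
  stop(structure(class = c("ncrus_no_resonance", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Extract resonance features from a transmission spectrum
#'
#' Locates the first thickness resonance as the interior magnitude maximum,
#' refines its frequency by a 3-point parabolic interpolation, and measures
#' the band where the magnitude stays within `window_db` of the peak (the
#' canonical analysis window is peak - 6 dB). Band edges are linearly
#' interpolated between grid points; the phase at resonance is read from the
#' unwrapped phase.
#'
#' @param spectrum A [complex_spectrum()].
#' @param window_db Width of the analysis window below the peak, dB;
#'   default 6.
#' @return Object of class `resonance_features`: `fres` (Hz),
#'   `peak_magnitude_db`, `band_lo`, `band_hi` (Hz), `relative_bandwidth`,
#'   `phase_at_resonance` (rad), and `partial` (TRUE when a band edge was
#'   truncated by the grid).
#' @section Errors: signals a condition of class `ncrus_no_resonance` when
#'   the spectrum has no interior maximum that decays by at least
#'   `window_db` on both sides within the grid.
#' @export
extract_resonance_features <- function(spectrum, window_db = 6) {
  stopifnot(inherits(spectrum, "complex_spectrum"), window_db > 0)
  f <- spectrum$frequencies
  mag <- magnitude_db(spectrum)
  ok <- is.finite(mag)
  if (sum(ok) < 5L) stop_no_resonance("too few finite magnitude bins")
  pk <- which.max(replace(mag, !ok, -Inf))
  n <- length(f)
  if (pk == 1L || pk == n) stop_no_resonance()
  lo_drop <- mag[pk] - min(mag[1:pk], na.rm = TRUE)
  hi_drop <- mag[pk] - min(mag[pk:n], na.rm = TRUE)
  partial <- FALSE
  if (lo_drop < window_db || hi_drop < window_db) {
    if (lo_drop < window_db / 2 || hi_drop < window_db / 2)
      stop_no_resonance(sprintf(
        "peak does not decay by %g dB within the grid", window_db / 2))
    partial <- TRUE
  }
  # parabolic refinement over the peak and its neighbours
  y <- mag[(pk - 1):(pk + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  delta <- if (is.finite(denom) && denom < 0) 0.5 * (y[1] - y[3]) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  fres <- f[pk] + delta * mean(diff(f[(pk - 1):(pk + 1)]))
  peak_db <- y[2] - 0.25 * (y[1] - y[3]) * delta
  thr <- peak_db - window_db
  cross <- function(idx_from, idx_to) {
    # walk from the peak outwards to the first crossing of thr
    idx <- idx_from
    step <- sign(idx_to - idx_from)
    while (idx != idx_to && mag[idx + step] >= thr) idx <- idx + step
    if (idx == idx_to) return(list(f = f[idx], truncated = TRUE))
    f1 <- f[idx]; f2 <- f[idx + step]
    m1 <- mag[idx]; m2 <- mag[idx + step]
    list(f = f1 + (thr - m1) / (m2 - m1) * (f2 - f1), truncated = FALSE)
  }
  lo <- cross(pk, 1L)
  hi <- cross(pk, n)
  phase <- spectrum_phase(spectrum)
  ph_res <- stats::approx(f, phase, xout = fres, rule = 2)$y
  structure(list(fres = fres,
                 peak_magnitude_db = peak_db,
                 band_lo = lo$f, band_hi = hi$f,
                 relative_bandwidth = (hi$f - lo$f) / fres,
                 phase_at_resonance = ph_res,
                 partial = partial || lo$truncated || hi$truncated,
                 window_db = window_db),
            class = "resonance_features")
}

#' @export
print.resonance_features <- function(x, ...) {
  cat(sprintf("Resonance: fres = %.2f kHz, peak %.2f dB\n",
              x$fres / 1e3, x$peak_magnitude_db))
  cat(sprintf("  -%g dB band: %.2f-%.2f kHz (relative bandwidth %.1f%%)\n",
              x$window_db, x$band_lo / 1e3, x$band_hi / 1e3,
              100 * x$relative_bandwidth))
  cat(sprintf("  phase at resonance: %.3f rad%s\n", x$phase_at_resonance,
              if (x$partial) "  [band truncated by grid]" else ""))
  invisible(x)
}

# analytic-signal envelope via the frequency-domain construction:
# zero the negative frequencies, double the positive ones, inverse transform
signal_envelope <- function(samples) {
  n <- length(samples)
  sp <- stats::fft(samples)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(sp * h, inverse = TRUE) / n)
}

#' Duration of a transmitted pulse
#'
#' Time between the first and last instants at which the analytic-signal
#' envelope exceeds the peak level plus `threshold_db` (a negative number;
#' default -20 dB). Crossing times are linearly interpolated between
#' samples. The duration is what sets the minimum transducer-leaf separation
#' (see [min_leaf_separation()]).
#'
#' @param wave A [waveform()] with a non-zero peak.
#' @param threshold_db Threshold relative to the envelope peak, dB; default
#'   -20.
#' @return Duration in seconds.
#' @export
pulse_duration <- function(wave, threshold_db = -20) {
  stopifnot(inherits(wave, "waveform"), threshold_db < 0)
  env <- signal_envelope(wave$samples)
  pk <- max(env)
  if (pk <= 0) stop("waveform has no non-zero peak")
  thr <- pk * 10^(threshold_db / 20)
  above <- env >= thr
  if (!any(above)) stop("envelope never exceeds threshold")
  i1 <- which(above)[1]
  i2 <- which(above)[length(which(above))]
  dt <- wave$sample_interval
  t1 <- if (i1 > 1) {
    (i1 - 2 + (thr - env[i1 - 1]) / (env[i1] - env[i1 - 1])) * dt
  } else 0
  t2 <- if (i2 < length(env)) {
    (i2 - 1 + (env[i2] - thr) / (env[i2] - env[i2 + 1])) * dt
  } else (length(env) - 1) * dt
  t2 - t1
}
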