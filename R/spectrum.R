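#' Complex transmission spectrum
#'
#' A frequency grid together with complex transmission values, the basic
#' container flowing between the forward model, the feature extractor and the
#' inverse solver. Magnitude and unwrapped-phase views are available through
#' [magnitude_db()] and [spectrum_phase()].
#'
#' @param frequencies Numeric vector, Hz, strictly increasing.
#' @param values Complex vector of transmission coefficients, same length.
#' @param meta Optional named list of provenance metadata (taper, seed, ...).
#' @return Object of class `complex_spectrum` with fields `frequencies`,
#'   `values`, `meta`.
#' @examples
#' s <- complex_spectrum(c(1e5, 2e5), c(0.5 + 0i, 0.25 + 0.1i))
#' magnitude_db(s)
#' @export
complex_spectrum <- function(frequencies, values, meta = list()) {
  stopifnot(is.numeric(frequencies), length(frequencies) >= 1L)
  if (any(!is.finite(frequencies)) || any(diff(frequencies) <= 0))
    stop("frequencies must be finite and strictly increasing")
  values <- as.complex(values)
  if (length(values) != length(frequencies))
    stop("frequencies and values must have the same length")
  structure(list(frequencies = frequencies, values = values, meta = meta),
            class = "complex_spectrum")
}

#' @export
print.complex_spectrum <- function(x, ...) {
  n <- length(x$frequencies)
  cat(sprintf("Complex spectrum: %d points, %.1f-%.1f kHz\n",
              n, min(x$frequencies) / 1e3, max(x$frequencies) / 1e3))
  m <- magnitude_db(x)
  ok <- is.finite(m)
  if (any(ok))
    cat(sprintf("  |T| peak %.2f dB at %.1f kHz\n",
                max(m[ok]), x$frequencies[ok][which.max(m[ok])] / 1e3))
  invisible(x)
}

#' @export
as.data.frame.complex_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies,
             real = Re(x$values), imag = Im(x$values))
}

#' @export
length.complex_spectrum <- function(x) length(x$frequencies)

#' Magnitude of a spectrum in decibels
#'
#' `20 log10 |T|` per frequency. Bins with zero magnitude return `-Inf`.
#'
#' @param spectrum A [complex_spectrum()].
#' @return Numeric vector of dB values.
#' @export
magnitude_db <- function(spectrum) {
  stopifnot(inherits(spectrum, "complex_spectrum"))
  20 * log10(Mod(spectrum$values))
}

#' Unwrapped phase of a spectrum
#'
#' Principal-value phase unwrapped along the frequency axis so that
#' consecutive samples never jump by more than pi.
#'
#' @param spectrum A [complex_spectrum()].
#' @return Numeric vector of phase values, radians.
#' @export
spectrum_phase <- function(spectrum) {
  stopifnot(inherits(spectrum, "complex_spectrum"))
  unwrap_phase(Arg(spectrum$values))
}

#' Unwrap a wrapped phase sequence
#'
#' Adds integer multiples of 2*pi so that consecutive differences lie in
#' (-pi, pi].
#'
#' @param phase Numeric vector of wrapped phase values, radians.
#' @return Unwrapped phase vector; first element unchanged.
#' @export
unwrap_phase <- function(phase) {
  if (length(phase) < 2L) return(phase)
  phase + 2 * pi * cumsum(c(0, round(-diff(phase) / (2 * pi))))
}

#' @export
plot.complex_spectrum <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  fk <- x$frequencies / 1e3
  graphics::plot(fk, magnitude_db(x), type = "l", xlab = "frequency (kHz)",
                 ylab = "|T| (dB)", ...)
  graphics::plot(fk, spectrum_phase(x), type = "l", xlab = "frequency (kHz)",
                 ylab = "phase (rad)", ...)
  invisible(x)
}

#' Read a transmission spectrum from CSV
#'
#' Two dialects are accepted, distinguished by header:
#' `frequency_hz,real,imag` (complex values) or
#' `frequency_hz,magnitude_db,phase_rad` (polar values, converted to complex).
#'
#' @param path Path to a CSV file.
#' @return A [complex_spectrum()]; `meta$dialect` records the dialect read.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty spectrum file: ", path)
  h <- names(df)
  if (identical(h[1:3], c("frequency_hz", "real", "imag"))) {
    vals <- complex(real = df$real, imaginary = df$imag)
    dialect <- "cartesian"
  } else if (identical(h[1:3], c("frequency_hz", "magnitude_db", "phase_rad"))) {
    vals <- 10^(df$magnitude_db / 20) * exp(1i * df$phase_rad)
    dialect <- "polar"
  } else {
    stop("unrecognised spectrum header in ", path, ": ",
         paste(h, collapse = ","))
  }
  if (any(diff(df$frequency_hz) <= 0)) {
    bad <- which(diff(df$frequency_hz) <= 0)[1] + 1L
    stop("non-monotone frequencies in ", path, " at data line ", bad)
  }
  complex_spectrum(df$frequency_hz, vals, meta = list(dialect = dialect,
                                                      source = path))
}

#' Write a transmission spectrum to CSV
#'
#' @param spectrum A [complex_spectrum()].
#' @param path Output path.
#' @param dialect `"cartesian"` (`frequency_hz,real,imag`) or `"polar"`
#'   (`frequency_hz,magnitude_db,phase_rad`).
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, dialect = c("cartesian", "polar")) {
  stopifnot(inherits(spectrum, "complex_spectrum"))
  dialect <- match.arg(dialect)
  df <- if (dialect == "cartesian") {
    as.data.frame(spectrum)
  } else {
    data.frame(frequency_hz = spectrum$frequencies,
               magnitude_db = magnitude_db(spectrum),
               phase_rad = spectrum_phase(spectrum))
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
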