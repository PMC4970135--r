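#' Insertion transmission coefficient of a leaf layer in air
#'
#' Closed-form plane-wave transmission at normal incidence through a single
#' homogeneous attenuating layer immersed in a fluid (air). With the
#' time-harmonic convention \eqn{e^{-i\omega t}} (propagation over distance
#' \eqn{d} multiplies by \eqn{e^{+ikd}}), the complex wavenumber in the layer
#' is \eqn{\tilde k = 2\pi f/c - i\,\alpha(f)} with
#' \eqn{\alpha(f) = \alpha_r (f/f_{ref})^n}, the complex layer impedance is
#' \eqn{Z = \rho\,2\pi f/\tilde k}, and the layer-only coefficient is
#' \deqn{T_{layer} = 1 / [\cos(\tilde k t) + (i/2)(z + 1/z)\sin(\tilde k t)]}
#' with \eqn{z = Z/Z_{air}}.
#'
#' What a substitution measurement records is the ratio of the received
#' spectrum with the leaf in the path to the spectrum of the bare air path,
#' so the returned insertion coefficient compensates the removed air column
#' of length `t`:
#' \deqn{T = T_{layer}\, e^{-i 2\pi f t / c_{air}}.}
#' This air-path phase term is what makes all four layer parameters
#' identifiable in the inverse problem; without it, \eqn{(t,\rho,c,\alpha_r)}
#' are determined only up to the scaling
#' \eqn{(st, \rho/s, sc, \alpha_r/s)}.
#'
#' For any passive layer (`alpha_res >= 0`) the magnitude satisfies
#' \eqn{|T| \le 1}.
#'
#' @param layer A [leaf_layer()].
#' @param air An [air_medium()]; default standard air.
#' @param frequencies Numeric vector of strictly positive frequencies, Hz.
#' @param insertion If `TRUE` (default) return the insertion (substitution)
#'   coefficient including the air-path compensation; if `FALSE` return the
#'   bare layer coefficient, useful for studying the identifiability of the
#'   inverse problem.
#' @return A [complex_spectrum()] of transmission coefficients.
#' @examples
#' vitis <- leaf_layer_from_report(174, 220, 68, 1625)
#' s <- layer_transmission(vitis, frequencies = seq(3e5, 1e6, by = 1e3))
#' max(magnitude_db(s)) # peak insertion loss, about -40 dB
#' @export
layer_transmission <- function(layer, air = air_medium(), frequencies,
                               insertion = TRUE) {
  stopifnot(inherits(layer, "leaf_layer"), inherits(air, "air_medium"))
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be finite and strictly positive")
  w <- 2 * pi * frequencies
  alpha <- alpha_at(layer, frequencies)
  # hyperbolic overflow guard: cosh(alpha*t) overflows near 710
  if (max(alpha) * layer$thickness > 700)
    stop("attenuation-thickness product too large: hyperbolic terms overflow ",
         sprintf("(max alpha*t = %.1f Np)", max(alpha) * layer$thickness))
  k <- w / layer$velocity - 1i * alpha
  Z <- layer$density * w / k
  z <- Z / air$impedance
  kt <- k * layer$thickness
  t_layer <- 1 / (cos(kt) + (0.5i) * (z + 1 / z) * sin(kt))
  values <- if (insertion) {
    t_layer * exp(-1i * w * layer$thickness / air$sound_speed)
  } else {
    t_layer
  }
  complex_spectrum(frequencies, values,
                   meta = list(model = "single_layer",
                               insertion = insertion))
}

#' Lossless thickness-resonance frequencies
#'
#' Half-wave resonance ladder of the layer: \eqn{f_n = n c / (2t)} for
#' `n = 1..max_order`. For a lossless layer between identical media the
#' transmission magnitude reaches exactly 1 at these frequencies.
#'
#' @param layer A [leaf_layer()].
#' @param max_order Highest harmonic order, integer >= 1.
#' @return Numeric vector of `max_order` strictly increasing frequencies, Hz.
#' @examples
#' lossless_resonances(leaf_layer(150e-6, 1000, 300, 0), 3) # 1, 2, 3 MHz
#' @export
lossless_resonances <- function(layer, max_order = 1L) {
  stopifnot(inherits(layer, "leaf_layer"),
            length(max_order) == 1L, max_order >= 1)
  seq_len(max_order) * layer$velocity / (2 * layer$thickness)
}
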