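#' Propagation medium (air)
#'
#' The surrounding gas in which the leaf is immersed. Its characteristic
#' acoustic impedance \eqn{Z = \rho c} sets the impedance mismatch against the
#' leaf tissue and hence the sharpness of the thickness resonance.
#'
#' @param sound_speed Speed of sound in the medium, m/s. Default 343 (air at
#'   about 20 degrees C).
#' @param density Density of the medium, kg/m^3. Default 1.2.
#' @return An object of class `air_medium` with fields `sound_speed`,
#'   `density` and derived `impedance` (Rayl).
#' @examples
#' air <- air_medium()
#' air$impedance # about 412 Rayl
#' @export
air_medium <- function(sound_speed = 343, density = 1.2) {
  stopifnot(is.numeric(sound_speed), length(sound_speed) == 1L, sound_speed > 0,
            is.numeric(density), length(density) == 1L, density > 0)
  structure(list(sound_speed = sound_speed, density = density,
                 impedance = density * sound_speed),
            class = "air_medium")
}

#' @export
print.air_medium <- function(x, ...) {
  cat(sprintf("Air medium: c = %g m/s, rho = %g kg/m^3, Z = %.1f Rayl\n",
              x$sound_speed, x$density, x$impedance))
  invisible(x)
}

#' Leaf as a homogeneous lossy acoustic layer
#'
#' The leaf is idealised as a single homogeneous attenuating plate
#' characterised by thickness `t`, density `rho`, thickness-direction sound
#' velocity `c` and an attenuation coefficient. Attenuation follows a
#' frequency power law \eqn{\alpha(f) = \alpha_r (f/f_{ref})^n} anchored at
#' the lossless first thickness resonance \eqn{f_{ref} = c/(2t)}, so
#' `alpha_res` is the attenuation at resonance in Np/m.
#'
#' Derived quantities: mass per area `LMA` \eqn{= \rho t} and effective
#' thickness-direction elastic modulus `c33` \eqn{= \rho c^2}.
#'
#' @param thickness Layer thickness, m.
#' @param density Layer density, kg/m^3.
#' @param velocity Thickness-direction sound speed, m/s.
#' @param alpha_res Attenuation at the reference resonance, Np/m. Must be
#'   non-negative (zero gives a lossless layer).
#' @param alpha_exponent Exponent `n` of the attenuation power law;
#'   default 1 (attenuation proportional to frequency).
#' @return An object of class `leaf_layer`.
#' @seealso [leaf_layer_from_report()] for construction from reporting units
#'   (um, g/m^2, MPa), [derived_quantities()], [report_units()].
#' @examples
#' vitis <- leaf_layer_from_report(174, 220, 68, 1625)
#' vitis$lma * 1e3   # 220 g/m^2
#' @export
leaf_layer <- function(thickness, density, velocity, alpha_res,
                       alpha_exponent = 1) {
  thickness <- unname(thickness); density <- unname(density)
  velocity <- unname(velocity); alpha_res <- unname(alpha_res)
  alpha_exponent <- unname(alpha_exponent)
  vals <- c(thickness, density, velocity)
  stopifnot(all(is.finite(vals)), all(vals > 0),
            is.finite(alpha_res), alpha_res >= 0,
            is.finite(alpha_exponent), alpha_exponent >= 0)
  structure(list(
    thickness = thickness, density = density, velocity = velocity,
    alpha_res = alpha_res, alpha_exponent = alpha_exponent,
    lma = density * thickness,          # kg/m^2
    c33 = density * velocity^2,         # Pa
    f_ref = velocity / (2 * thickness)  # Hz, lossless first resonance
  ), class = "leaf_layer")
}

#' @export
print.leaf_layer <- function(x, ...) {
  r <- report_units(x)
  cat("Leaf layer (homogeneous lossy plate)\n")
  cat(sprintf("  t    = %8.2f um\n", r$thickness_um))
  cat(sprintf("  LMA  = %8.2f g/m^2\n", r$lma_g_m2))
  cat(sprintf("  c33  = %8.3f MPa\n", r$c33_mpa))
  cat(sprintf("  alpha= %8.1f Np/m at resonance (exponent n = %g)\n",
              r$alpha_np_m, x$alpha_exponent))
  cat(sprintf("  rho  = %8.1f kg/m^3, c = %.1f m/s, f_ref = %.1f kHz\n",
              x$density, x$velocity, x$f_ref / 1e3))
  invisible(x)
}

#' Internal layer parameters from reported quantities
#'
#' Inverts the reporting parameterisation: given thickness, mass per area and
#' thickness-direction elastic modulus, returns density, velocity and the
#' lossless first-resonance frequency. `rho = LMA/t`, `c = sqrt(c33/rho)`,
#' `f1 = c/(2t)`.
#'
#' @param thickness Thickness, m.
#' @param lma Mass per area, kg/m^2.
#' @param c33 Elastic modulus, Pa.
#' @return List with `density` (kg/m^3), `velocity` (m/s) and `f1_lossless`
#'   (Hz).
#' @examples
#' derived_quantities(174e-6, 220e-3, 68e6) # rho ~ 1264 kg/m^3, c ~ 232 m/s
#' @export
derived_quantities <- function(thickness, lma, c33) {
  stopifnot(is.finite(thickness), thickness > 0,
            is.finite(lma), lma > 0, is.finite(c33), c33 > 0)
  density <- lma / thickness
  velocity <- sqrt(c33 / density)
  list(density = density, velocity = velocity,
       f1_lossless = velocity / (2 * thickness))
}

#' Build a leaf layer from values in reporting units
#'
#' Convenience constructor taking the units in which leaf parameters are
#' customarily tabulated: micrometres, g/m^2, MPa and Np/m.
#'
#' @param thickness_um Thickness, um.
#' @param lma_g_m2 Mass per area, g/m^2.
#' @param c33_mpa Elastic modulus, MPa.
#' @param alpha_np_m Attenuation at resonance, Np/m.
#' @param alpha_exponent Attenuation power-law exponent, default 1.
#' @return A [leaf_layer()].
#' @export
leaf_layer_from_report <- function(thickness_um, lma_g_m2, c33_mpa, alpha_np_m,
                                   alpha_exponent = 1) {
  t <- thickness_um * 1e-6
  d <- derived_quantities(t, lma_g_m2 * 1e-3, c33_mpa * 1e6)
  leaf_layer(t, d$density, d$velocity, alpha_np_m, alpha_exponent)
}

#' Report an object in customary units
#'
#' Converts SI-internal quantities to the units used when tabulating leaf
#' acoustic parameters: um, g/m^2, MPa, Np/m, kHz. The conversion is exact
#' and invertible.
#'
#' @param x A `leaf_layer` or `leaf_fit` object.
#' @param ... Unused.
#' @return A list of named values in reporting units.
#' @export
report_units <- function(x, ...) UseMethod("report_units")

#' @export
report_units.leaf_layer <- function(x, ...) {
  list(thickness_um = x$thickness * 1e6,
       lma_g_m2 = x$lma * 1e3,
       c33_mpa = x$c33 / 1e6,
       alpha_np_m = alpha_at(x, x$f_ref),
       f_ref_khz = x$f_ref / 1e3)
}

# attenuation power law evaluated at frequency f (Hz)
alpha_at <- function(layer, f) {
  layer$alpha_res * (f / layer$f_ref)^layer$alpha_exponent
}
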