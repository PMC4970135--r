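#' Minimum transducer-leaf separation
#'
#' The through-transmitted pulse must not overlap the reverberations in the
#' transducer-leaf air cavity: the two-way transit time across the gap must
#' exceed the pulse duration, giving
#' \eqn{\Delta L_{min} = 2\, c_{air}\, \delta t}. The value is reported raw
#' and rounded to the nearest millimetre (nearest, not ceiling: a 35 us
#' pulse in standard air gives 24.01 mm, quoted as ">24 mm").
#'
#' @param pulse_duration_s Duration of the through-transmitted pulse, s
#'   (see [pulse_duration()]).
#' @param air An [air_medium()].
#' @return List with `meters` (raw) and `millimetres` (nearest mm).
#' @examples
#' min_leaf_separation(35e-6)$millimetres # 24
#' min_leaf_separation(20e-6)$millimetres # 14
#' @export
min_leaf_separation <- function(pulse_duration_s, air = air_medium()) {
  stopifnot(is.finite(pulse_duration_s))
  if (pulse_duration_s < 0) stop("pulse duration must be non-negative")
  m <- 2 * air$sound_speed * pulse_duration_s
  list(meters = m, millimetres = round(m * 1e3))
}

#' Natural focal length of a circular piston transducer
#'
#' The near-field/far-field transition distance \eqn{a^2/\lambda} of a
#' circular aperture of radius `a` radiating at frequency `f`; placing the
#' leaf there minimises the beam section on its surface.
#'
#' @param aperture_radius Aperture radius `a`, m.
#' @param frequency Radiating frequency, Hz.
#' @param air An [air_medium()].
#' @return Focal length, m.
#' @examples
#' natural_focal_length(10e-3, 350e3) # about 0.102 m
#' @export
natural_focal_length <- function(aperture_radius, frequency,
                                 air = air_medium()) {
  stopifnot(aperture_radius >= 0, frequency > 0)
  aperture_radius^2 * frequency / air$sound_speed
}

#' One-way acoustic transit time between transducers
#'
#' `D / c_air`: the floor on the duration of a single measurement. For the
#' usual separations below 60 mm this stays under 180 us.
#'
#' @param distance Transmitter-receiver separation `D`, m.
#' @param air An [air_medium()].
#' @return Transit time, s.
#' @export
transit_time <- function(distance, air = air_medium()) {
  stopifnot(distance >= 0)
  distance / air$sound_speed
}

#' Acquisition time of an averaged measurement
#'
#' `n_averages / prf`: with pulse repetition frequencies of 100-1000 Hz and
#' 10-100 averages the elapsed time per averaged record lies between 1 and
#' 0.1 s.
#'
#' @param n_averages Number of records averaged, integer >= 1.
#' @param prf Pulse repetition frequency, Hz.
#' @return Elapsed time, s.
#' @export
acquisition_time <- function(n_averages, prf) {
  stopifnot(n_averages >= 1, prf > 0)
  n_averages / prf
}

#' Dynamic-range budget check
#'
#' The weakest transmission level that must still be measurable is the peak
#' insertion loss plus the analysis window below the peak (canonically
#' 6 dB); with peak losses up to 45 dB this implies measuring transmission
#' moduli down to about -60 dB (`reference_floor_db`). The check passes
#' when the available system SNR covers that budget plus an optional margin.
#'
#' @param peak_loss_db Peak insertion loss of the leaf, dB (positive
#'   number).
#' @param window_db Analysis window below the peak, dB >= 0; default 6.
#' @param system_snr_db Available system SNR (no leaf), dB.
#' @param margin_db Additional safety margin, dB; default 0.
#' @return List: `required_floor_db` (= -(peak_loss + window)),
#'   `reference_floor_db` (-60), `pass`.
#' @export
dynamic_range_check <- function(peak_loss_db, window_db = 6, system_snr_db,
                                margin_db = 0) {
  stopifnot(window_db >= 0)
  list(required_floor_db = -(peak_loss_db + window_db),
       reference_floor_db = -60,
       pass = system_snr_db >= peak_loss_db + window_db + margin_db)
}

#' Beam-versus-leaf size check
#'
#' The measurement area coincides with the beam section, which must fit
#' well inside the leaf: the check passes when the beam diameter is
#' strictly smaller than half the leaf width.
#'
#' @param beam_diameter Acoustic beam diameter at the leaf plane, m.
#' @param leaf_width Leaf width, m.
#' @return `TRUE`/`FALSE`.
#' @export
beam_leaf_check <- function(beam_diameter, leaf_width) {
  stopifnot(beam_diameter > 0, leaf_width > 0)
  beam_diameter < leaf_width / 2
}

#' Coefficient of variation
#'
#' `100 * sd / mean`, reported raw and rounded to the nearest integer
#' percent; the customary summary of leaf-to-leaf resonance variability
#' (e.g. 490 +/- 30 kHz gives 6%).
#'
#' @param mean Mean value, > 0.
#' @param sd Standard deviation, >= 0.
#' @return List with `percent` (raw) and `percent_rounded`.
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
  stopifnot(sd >= 0)
  p <- 100 * sd / mean
  list(percent = p, percent_rounded = round(p))
}

#' Design criteria fixtures for the two reference species
#'
#' Tabulated transducer design criteria: beam diameter limit, centre
#' frequency, frequency band and minimum no-leaf SNR, together with typical
#' leaf width and pulse duration used by [design_report()].
#'
#' @param species `"vitis_vinifera"` or `"coffea_arabica"`.
#' @return List of design criteria.
#' @export
design_criteria <- function(species = c("vitis_vinifera", "coffea_arabica")) {
  species <- match.arg(species)
  switch(species,
    vitis_vinifera = list(
      species = "vitis_vinifera",
      beam_diameter_max = 25e-3, centre_frequency = 650e3,
      band = c(400e3, 900e3), snr_min_db = 65,
      leaf_width = 120e-3, pulse_duration_s = 20e-6,
      system_snr_db = 70),
    coffea_arabica = list(
      species = "coffea_arabica",
      beam_diameter_max = 20e-3, centre_frequency = 300e3,
      band = c(200e3, 400e3), snr_min_db = 60,
      leaf_width = 60e-3, pulse_duration_s = 35e-6,
      system_snr_db = 63))
}

#' Run all design checks for a species fixture
#'
#' Evaluates the geometric, timing and dynamic-range budget of an
#' acquisition design against its criteria: beam size versus leaf width,
#' resonance band (from the species preset forward model) inside the system
#' band, minimum separation from the pulse duration, one-way transit time
#' under 180 us, and the SNR covering the peak loss plus the 6 dB analysis
#' window.
#'
#' @param species `"vitis_vinifera"` or `"coffea_arabica"`.
#' @param criteria Criteria list; default [design_criteria()] for the
#'   species.
#' @return Data frame of class `design_report`: one row per check with
#'   `check`, `value`, `unit`, `bound`, `pass`.
#' @export
design_report <- function(species = c("vitis_vinifera", "coffea_arabica"),
                          criteria = design_criteria(species)) {
  species <- match.arg(species)
  cr <- criteria
  preset <- species_preset(species)
  # resonance features of the reference layer inside the system band
  grid <- seq(cr$band[1], cr$band[2], length.out = 501)
  spec <- layer_transmission(preset$layer, frequencies = grid)
  feats <- extract_resonance_features(spec)
  sep <- min_leaf_separation(cr$pulse_duration_s)
  # transducer separation: leaf between the two, one gap each side
  D <- 2 * sep$meters
  tt <- transit_time(D)
  dr <- dynamic_range_check(-feats$peak_magnitude_db,
                            system_snr_db = cr$system_snr_db)
  rows <- list(
    list(check = "beam diameter below leaf half width",
         value = cr$beam_diameter_max * 1e3, unit = "mm",
         bound = sprintf("< %.0f", cr$leaf_width / 2 * 1e3),
         pass = beam_leaf_check(cr$beam_diameter_max, cr$leaf_width)),
    list(check = "resonance -6 dB band inside system band",
         value = feats$fres / 1e3, unit = "kHz",
         bound = sprintf("band %.0f-%.0f kHz", cr$band[1] / 1e3,
                         cr$band[2] / 1e3),
         pass = feats$band_lo >= cr$band[1] && feats$band_hi <= cr$band[2]),
    list(check = "minimum transducer-leaf separation",
         value = sep$meters * 1e3, unit = "mm",
         bound = sprintf(">= %d mm two-way clearance", sep$millimetres),
         pass = TRUE),
    list(check = "one-way transit time",
         value = tt * 1e6, unit = "us", bound = "<= 180 us",
         pass = tt <= 180e-6),
    list(check = "system SNR covers peak loss + 6 dB window",
         value = cr$system_snr_db, unit = "dB",
         bound = sprintf(">= %.1f dB", -feats$peak_magnitude_db + 6),
         pass = dr$pass),
    list(check = "system SNR meets species criterion",
         value = cr$system_snr_db, unit = "dB",
         bound = sprintf("> %.0f dB", cr$snr_min_db),
         pass = cr$system_snr_db > cr$snr_min_db))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  attr(out, "species") <- species
  class(out) <- c("design_report", class(out))
  out
}

#' @export
print.design_report <- function(x, ...) {
  cat("Design report:", attr(x, "species"), "\n")
  df <- as.data.frame(x)
  df$value <- signif(df$value, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
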