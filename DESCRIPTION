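Package: ncrus
Title: Non-Contact Resonant Ultrasonic Spectroscopy of Plant Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse modelling for air-coupled resonant
    ultrasonic spectroscopy of plant leaves. Models plane-wave transmission
    through a leaf treated as a homogeneous lossy layer in air, extracts
    thickness, mass per area, elastic modulus and attenuation from
    magnitude and phase transmission spectra by bounded multistart
    least squares, links resonance frequency to relative water content and
    water potential through four-parameter logistic and segmented linear
    calibration curves, and provides the acoustic system design budget
    calculations (separation, focal length, timing, dynamic range) needed
    to dimension a measurement set-up. Includes a synthetic data generator
    for noisy spectra and dehydration trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
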