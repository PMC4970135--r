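---
title: "Methods: leaf thickness-resonance spectroscopy in ncrus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf thickness-resonance spectroscopy in ncrus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncrus)
```

## The measurement and the model

A plant leaf held in air between two air-coupled ultrasonic transducers
behaves as a thin resonant plate: the enormous impedance mismatch between
air (about 412 Rayl) and leaf tissue (order 10^5 Rayl) traps acoustic energy
in the thickness direction, and transmission through the leaf peaks at the
half-wave thickness resonances. The frequency, depth and width of the first
resonance encode the leaf's thickness `t`, density `rho`, thickness-direction
sound velocity `c` and attenuation, and through them the quantities a plant
physiologist cares about: mass per area `LMA = rho * t`, effective elastic
modulus `c33 = rho * c^2`, and — via calibration — relative water content
(RWC) and water potential.

`ncrus` models the leaf as a single homogeneous lossy layer. With the
time-harmonic convention `exp(-i omega t)` (so propagation over a distance
`d` multiplies the field by `exp(+i k d)`), the layer has complex wavenumber

    k = 2 pi f / c - i alpha(f),   alpha(f) = alpha_r (f / f_ref)^n,

anchored at the lossless first resonance `f_ref = c / (2 t)`, complex
impedance `Z = rho * 2 pi f / k`, and layer-only transmission

    T_layer = 1 / [ cos(k t) + (i/2) (z + 1/z) sin(k t) ],   z = Z / Z_air.

What an instrument records is a *substitution* (insertion) measurement: the
spectrum with the leaf in the path divided by the spectrum of the bare air
path. The package therefore returns

    T = T_layer * exp(-i 2 pi f t / c_air),

compensating the removed air column. This factor is not cosmetic: without
it the forward model is invariant under the one-parameter family
`(s t, rho / s, s c, alpha_r / s)` and the inverse problem cannot separate
thickness from velocity. A dedicated test demonstrates that degeneracy with
the air term disabled.

Under this sign convention `T_layer` is purely real (and negative) at the
lossless resonances; the package tests assert the zero crossing of its
imaginary part there, which is the convention-independent content of the
"phase crosses the resonance" statement.

Air defaults are `c_air = 343` m/s and `rho_air = 1.2` kg/m^3 (about 20 C),
both configurable through `air_medium()`.

### Attenuation law

Only the attenuation *at resonance* is identifiable from a single resonance,
so the exponent `n` of the power law is held fixed during fitting (default
`n = 1`, attenuation proportional to frequency, the common behaviour of
soft hydrated tissue in this band) and the reported attenuation is the law
evaluated at the fitted layer's own reference resonance, which equals the
fitted `alpha_r` exactly.

## Feature extraction

`extract_resonance_features()` locates the interior magnitude maximum,
refines the peak frequency with a 3-point parabolic interpolation (making
`fres` grid-independent at kHz precision on the grids used here), and
interpolates the crossings of the peak-minus-6-dB level for the band edges.
The 6 dB window is the canonical analysis band for these spectra: the
resonances of interest have 6 dB relative bandwidths of roughly 25-70
percent, and a deeper window would run into the noise floor of a realistic
dynamic-range budget. A spectrum whose maximum sits on the grid edge, or
that decays by less than 3 dB on either side, is rejected as having no
resonance in band; decay between 3 and 6 dB is accepted but flagged partial.

## The inverse problem

`fit_leaf_spectrum()` minimises the root-mean-square deviation

    epsilon = sqrt( mean_f [ w_m dm^2 + w_p dphi^2 ] )

over the 6 dB window, where `dm` is the magnitude difference scaled by the
*measured* in-window peak and `dphi` the unwrapped phase difference in
radians, with unit weights by default. Scaling both spectra by the measured
peak (rather than each by its own) is deliberate: peak-normalising model and
data separately discards the absolute insertion-loss level, which is what
carries the density information, and leaves a near-degenerate valley in
`(rho, alpha_r)` — we observed fits running density to its bound with
epsilon around 1e-5 under that convention.

The objective is multimodal. The optimiser:

1. ties velocity to the observed peak (`c = 2 t fres`) and lays a coarse
   logarithmic grid over `(t, rho, alpha_r)` (24 x 6 x 8 by default) on that
   manifold,
2. ranks the candidates by epsilon and polishes the best twelve with
   bounded Levenberg-Marquardt (`minpack.lm::nls.lm`) in log-parameters,
3. adds four seeded Latin-hypercube restarts over the full box as a
   safeguard against an atypical peak, and returns the best local optimum.

Pure random multistart (Latin hypercube alone, 16 restarts) missed the
global basin on roughly a third of randomly drawn resonant layers during
development; the resonance-informed grid removed every such failure while
keeping the fit under a second on a 700-point spectrum. Default bounds are
`t` in [20, 1000] um, `rho` in [200, 2000] kg/m^3, `c` in [30, 1000] m/s and
`alpha_r` in [10, 20000] Np/m, generous envelopes around all broadleaf
values we are aware of. The seed is mandatory and every fit is deterministic
given (spectrum, config, seed).

Fits are flagged when a parameter lands on a bound. Layers whose
attenuation-thickness product is so large that no interior resonance
survives (roughly `alpha * t > 2` Np) fail the resonance precondition and
are rejected before fitting — there is no information to invert.

## Physiological calibration

Two curve families link resonance frequency to water status:

* **Four-parameter logistic** (`fit_logistic4()`),
  `y = A + (B - A) / (1 + exp(-(x - x0)/s))`: the resonance frequency
  against RWC is a falling sigmoid whose inflection `x0` is the operational
  proxy for the turgor loss point. The exponential form with an explicit
  inflection parameter was chosen so the physiologically meaningful
  quantity is a direct coefficient. Fitting uses bounded
  Levenberg-Marquardt from a 3 x 3 grid of starts in `(x0, s)`; parameters
  pinned at their bounds (e.g. on straight-line data, which drives the
  asymptotes outward) are flagged as a degenerate sigmoid.
* **Segmented linear** (`fit_segmented_linear()`): water potential against
  resonance frequency is two lines joined continuously at a break point.
  The join is found by exhaustive search over all midpoints between
  consecutive distinct `x` values — each midpoint indexes a distinguishable
  model — followed by continuous refinement with `optimize()` between the
  neighbouring candidates. Collinear data are detected by comparing the
  broken-stick and single-line residuals and returned as a flagged
  single-line fallback.

Both fitters are invariant to point order and report adjusted R^2; the
simple `linear_fit()` adds the Pearson correlation. Calibration direction
follows the convention of each relationship (fres against RWC; water
potential against fres); both directions are available by swapping the
arguments.

## The synthetic generator

`dehydration_series()` emulates a free-transpiration dehydration experiment
with known ground truth. Its defaults are the study conditions of the
reference species:

* *Coffea arabica*: layer 210 um / 153 g m^-2 / 12 MPa / 1070 Np m^-1, band
  200-400 kHz, resonance falling 350 to 225 kHz as RWC goes 1 to 0.70;
* *Vitis vinifera*: layer 174 um / 220 g m^-2 / 68 MPa / 1625 Np m^-1, band
  400-900 kHz, resonance 580 to 460 kHz as water potential goes 0 to
  -25 bar (RWC 1 to 0.78);
* *Viburnum tinus*: a synthetic stand-in layer (no tabulated parameter row
  exists for this species) placed near the observed 490 kHz mean resonance,
  encoding the observed 33 percent resonance drop over RWC 1 to 0.70.

RWC declines linearly over the steps. The resonance trajectory is a
four-parameter logistic whose asymptotes are solved exactly from the two
endpoint frequencies given the inflection (at the turgor loss point,
default RWC 0.85 — a generator choice, configurable, since no tabulated RWC
value for the TLP exists) and scale `s = (1 - RWC_end)/8`, chosen so the
sigmoid's transition occupies the central third of the trajectory, as
observed dehydration curves do. Water potential follows a segmented linear
model in fres with its join at the TLP; a quarter of the total potential
drop is placed above the join (gentle pre-TLP slope, steep post-TLP slope),
again a documented generator choice. The Coffea potential endpoint
(-16 bar) is likewise a generator choice consistent with the observed range
of that species under drought.

At each step the true layer is adjusted: thickness shrinks linearly in
`1 - RWC`, reaching 10 percent at the dry end, density is held, and the
velocity is retuned so the lossless resonance tracks the trajectory — the
remainder of the frequency change is thereby absorbed by the elastic
modulus. The split between shrinkage and stiffness is a modelling choice;
both mechanisms are known to contribute and their ratio is not constrained
by available data.

Spectral noise is circularly-symmetric complex Gaussian, scaled so the
in-band SNR (mean signal power over mean noise power across the grid)
equals the request; noise is applied in the spectral domain. Waveform-level
simulation is available through the signal-processing functions for
integration tests. Every synthetic observation carries its generating layer
and seed in its metadata, and identical generator inputs give byte-identical
output.

What the generator does *not* emulate: leaf-to-leaf biological variability,
spatial inhomogeneity across the blade (veins, curvature), multi-layer
anatomy (palisade versus spongy mesophyll), diffraction and beam-spreading,
or transducer response. Passing tests therefore demonstrate the
correctness of the computational chain under the homogeneous-layer model,
not the adequacy of that model for any particular real leaf.

## System design calculations

The design module collects the budget arithmetic for dimensioning a
measurement set-up: minimum transducer-leaf separation `2 c_air dt` (the
two-way gap transit must outlast the pulse; reported raw and rounded to the
*nearest* millimetre, which reproduces the worked values 24 mm at 35 us and
14 mm at 20 us), natural focal length `a^2 f / c_air`, one-way transit time
`D / c_air` against the 180 us single-measurement budget, acquisition time
`n / PRF`, the dynamic-range budget (peak loss plus the 6 dB window against
system SNR, with the -60 dB reference floor), the beam-inside-half-leaf
check, and the coefficient of variation used to summarise leaf-to-leaf
resonance spread. `design_report()` runs the full checklist for the two
reference species fixtures.

## Numerical choices and degenerate inputs

* All internal units are SI; `report_units()` converts exactly to the
  customary um / g m^-2 / MPa / Np m^-1 / kHz.
* The forward model rejects non-positive frequencies and layers whose
  hyperbolic terms would overflow (`alpha * t > 700` Np).
* Optimisation is in log-parameters, which makes the box constraints
  scale-free and keeps the Jacobian well conditioned across the four
  decades spanned by the bounds.
* Phase unwrapping adds the multiple of 2 pi that keeps consecutive
  differences in (-pi, pi]; the model and data phases in the residual are
  each unwrapped from the window's first bin.
* The parabolic peak refinement clamps its offset to half a grid step and
  falls back to the raw arg-max on a degenerate (non-concave) triple.
* Ties in the segmented-linear grid search resolve to the first minimum;
  the subsequent continuous refinement makes the choice immaterial on
  non-degenerate data.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the Table-row round trips
on 1 kHz grids (701 and 451 points), the random-layer recovery suite on 20
draws of 600-point spectra, the noisy-inversion study on 30 replicates at
40 dB SNR, calibration recovery on 60 replicates per family, and the
dehydration closure on a 10-step noiseless series. These sizes were chosen
so the whole suite completes in about a minute on a single core while
leaving each statistical check with comfortable resolution; all of them
scale up linearly if heavier validation is wanted.

## Known limitations

* Single homogeneous layer, normal incidence, plane waves: no multi-layer
  anatomy, oblique incidence or diffraction corrections.
* One resonance per fit; joint multi-harmonic fitting is out of scope.
* The attenuation exponent is fixed, not estimated.
* Uncertainty is summarised only through restart spread and the epsilon
  misfit; no formal confidence intervals.
* The turgor-loss-point placement and the thickness/stiffness split in the
  generator are conventions, not measurements; conclusions about real
  leaves require instrument calibration data.
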