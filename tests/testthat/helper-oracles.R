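# Independent oracles, coded separately from the package internals.

# Brute-force scalar (non-vectorised) evaluation of the single-layer
# insertion transmission, written directly from the closed form.
oracle_insertion <- function(f, thickness, density, velocity, alpha_res,
                             alpha_exponent = 1, c_air = 343, rho_air = 1.2) {
  vapply(f, function(fi) {
    omega <- 2 * pi * fi
    f_ref <- velocity / (2 * thickness)
    a <- alpha_res * (fi / f_ref)^alpha_exponent
    k <- complex(real = omega / velocity, imaginary = -a)
    Z <- density * omega / k
    zr <- Z / (rho_air * c_air)
    tl <- 1 / (cos(k * thickness) +
                 (1i / 2) * (zr + 1 / zr) * sin(k * thickness))
    tl * exp(-1i * omega * thickness / c_air)
  }, complex(1))
}

# arg-max of |T| by brute force on a fine grid (10 Hz steps)
oracle_peak_frequency <- function(layer, f_lo, f_hi, step = 10) {
  grid <- seq(f_lo, f_hi, by = step)
  mods <- Mod(oracle_insertion(grid, layer$thickness, layer$density,
                               layer$velocity, layer$alpha_res,
                               layer$alpha_exponent))
  grid[which.max(mods)]
}

# cumulative wrapped-difference phase unwrapping (independent formulation)
oracle_unwrap <- function(ph) {
  out <- ph
  for (i in seq_along(ph)[-1]) {
    d <- ph[i] - ph[i - 1]
    d <- ((d + pi) %% (2 * pi)) - pi
    if (d == -pi) d <- pi
    out[i] <- out[i - 1] + d
  }
  out
}

# random leaf-like layer that exhibits a usable resonance on its grid;
# returns layer plus a grid bracketing the first resonance
random_resonant_layer <- function() {
  repeat {
    t <- runif(1, 8e-5, 6e-4)
    rho <- runif(1, 300, 1800)
    cc <- runif(1, 60, 600)
    a <- runif(1, 200, 6000)
    layer <- leaf_layer(t, rho, cc, a)
    f1 <- layer$f_ref
    grid <- seq(max(0.5 * f1, 2e4), 1.8 * f1, length.out = 600)
    spec <- layer_transmission(layer, frequencies = grid)
    ok <- tryCatch({
      ft <- extract_resonance_features(spec)
      !ft$partial
    }, error = function(e) FALSE)
    if (ok) return(list(layer = layer, grid = grid, spectrum = spec))
  }
}

table3_vitis <- function() leaf_layer_from_report(174, 220, 68, 1625)
table3_coffea <- function() leaf_layer_from_report(210, 153, 12, 1070)
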