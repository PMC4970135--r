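test_that("rms deviation follows its closed form", {
  f <- seq(3e5, 4e5, by = 2e3)
  vitis <- table3_vitis()
  s <- layer_transmission(vitis, frequencies = f)
  expect_equal(rms_deviation(s, s), 0, tolerance = 1e-15)
  # constant relative magnitude offset d, zero phase error -> epsilon = d
  d <- 0.03
  peak <- max(Mod(s$values))
  off <- complex_spectrum(f, s$values + d * peak * exp(1i * Arg(s$values)))
  expect_equal(rms_deviation(s, off), d, tolerance = 1e-6)
  # phase-only offset of p rad -> epsilon = p (weights 1, 1)
  p <- 0.05
  rot <- complex_spectrum(f, s$values * exp(1i * p))
  eps <- rms_deviation(s, rot)
  expect_gt(eps, 0.9 * p) # magnitude term is zero; phase term dominates
  expect_lt(abs(eps - p) / p, 0.05)
  expect_error(rms_deviation(s, s, window = c(3e5, 3.05e5)), "5 grid points")
})

test_that("rms deviation of random perturbations matches its expectation", {
  # complex circular noise of relative sd q added to a flat spectrum:
  # magnitude residual ~ N(0, q^2/2), phase residual ~ N(0, q^2/2),
  # so E[eps^2] = q^2 and eps concentrates around q
  set.seed(41)
  f <- seq(1e5, 2e5, by = 1e3)
  n <- length(f)
  base <- complex_spectrum(f, rep(1 + 0i, n))
  q <- 0.01
  eps <- replicate(500, {
    pert <- complex(real = 1 + rnorm(n, sd = q / sqrt(2)),
                    imaginary = rnorm(n, sd = q / sqrt(2)))
    rms_deviation(base, complex_spectrum(f, pert))
  })
  se <- sd(eps) / sqrt(length(eps))
  expect_lt(abs(mean(eps) - q), 3 * se + 0.002 * q)
})

test_that("the inverse solver recovers the tabulated leaf parameters", {
  cases <- list(
    list(layer = table3_vitis(), grid = seq(3e5, 1e6, by = 1e3),
         want = c(t = 174, lma = 220, c33 = 68, alpha = 1625)),
    list(layer = table3_coffea(), grid = seq(1.5e5, 6e5, by = 1e3),
         want = c(t = 210, lma = 153, c33 = 12, alpha = 1070)))
  for (cs in cases) {
    s <- layer_transmission(cs$layer, frequencies = cs$grid)
    fit <- fit_leaf_spectrum(s, fit_config(seed = 1))
    r <- report_units(fit)
    got <- c(r$thickness_um, r$lma_g_m2, r$c33_mpa, r$alpha_np_m)
    expect_lt(max(abs(got - cs$want) / cs$want), 0.01)
    expect_true(fit$converged)
    expect_false(any(fit$at_bound))
    expect_lt(fit$epsilon, 1e-8)
  }
})

test_that("noiseless round trips recover random layers within 0.5 percent", {
  set.seed(1234)
  for (i in 1:20) {
    rl <- random_resonant_layer()
    fit <- fit_leaf_spectrum(rl$spectrum, fit_config(seed = 100 + i))
    rel <- abs(coef(fit) - c(thickness = rl$layer$thickness,
                             density = rl$layer$density,
                             velocity = rl$layer$velocity,
                             alpha_res = rl$layer$alpha_res)) /
      abs(coef(fit) * 0 + c(rl$layer$thickness, rl$layer$density,
                            rl$layer$velocity, rl$layer$alpha_res))
    expect_lt(max(rel), 0.005)
  }
})

test_that("fits are deterministic given spectrum, config and seed", {
  vitis <- table3_vitis()
  s <- synthesize_spectrum(vitis, frequencies = seq(3e5, 1e6, by = 2e3),
                           snr_db = 35, seed = 9)
  f1 <- fit_leaf_spectrum(s, fit_config(seed = 7))
  f2 <- fit_leaf_spectrum(s, fit_config(seed = 7))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$epsilon, f2$epsilon)
})

test_that("the returned fit is at least as good as every candidate start", {
  # monotone improvement: epsilon of the polished optimum cannot exceed the
  # epsilon of any start, in particular the best coarse candidate
  coffea <- table3_coffea()
  s <- synthesize_spectrum(coffea, frequencies = seq(1.5e5, 6e5, by = 1e3),
                           snr_db = 30, seed = 2)
  fit <- fit_leaf_spectrum(s, fit_config(seed = 5))
  sel <- fit$window_idx
  meas <- complex_spectrum(s$frequencies[sel], s$values[sel])
  set.seed(5)
  for (i in 1:10) {
    trial <- leaf_layer(runif(1, 2e-5, 1e-3), runif(1, 200, 2000),
                        runif(1, 30, 1000), runif(1, 10, 2e4))
    eps_trial <- rms_deviation(meas,
      layer_transmission(trial, frequencies = meas$frequencies))
    expect_lte(fit$epsilon, eps_trial)
  }
})

test_that("noisy spectra at 40 dB SNR are inverted to a few percent", {
  vitis <- table3_vitis()
  grid <- seq(3e5, 1e6, by = 2e3)
  truth <- coef(fit_leaf_spectrum(
    layer_transmission(vitis, frequencies = grid), fit_config(seed = 1)))
  rel_err <- sapply(1:30, function(i) {
    s <- synthesize_spectrum(vitis, frequencies = grid, snr_db = 40,
                             seed = 1000 + i)
    fit <- fit_leaf_spectrum(s, fit_config(seed = i))
    abs(coef(fit) - truth) / truth
  })
  expect_lt(max(apply(rel_err, 1, median)), 0.05)
})

test_that("without the air-path term the inverse problem is degenerate", {
  # along (s t, rho/s, s c, alpha/s) the bare-layer spectrum is invariant,
  # so the misfit stays flat; the insertion convention lifts the degeneracy
  vitis <- table3_vitis()
  f <- seq(3e5, 1e6, by = 2e3)
  bare <- layer_transmission(vitis, frequencies = f, insertion = FALSE)
  ins <- layer_transmission(vitis, frequencies = f, insertion = TRUE)
  eps_bare <- eps_ins <- numeric(0)
  for (s in c(0.8, 0.9, 1.1, 1.25)) {
    scaled <- leaf_layer(s * vitis$thickness, vitis$density / s,
                         s * vitis$velocity, vitis$alpha_res / s)
    eps_bare <- c(eps_bare, rms_deviation(bare,
      layer_transmission(scaled, frequencies = f, insertion = FALSE)))
    eps_ins <- c(eps_ins, rms_deviation(ins,
      layer_transmission(scaled, frequencies = f, insertion = TRUE)))
  }
  expect_lt(max(eps_bare), 1e-10)   # flat valley: unidentifiable
  expect_gt(min(eps_ins), 1e-2)     # air-path phase separates the family
})

test_that("fitting a spectrum without resonance fails loudly", {
  f <- seq(2e5, 5e5, by = 1e3)
  s <- complex_spectrum(f, seq(1, 0.01, length.out = length(f)) + 0i)
  expect_error(fit_leaf_spectrum(s, fit_config(seed = 1)),
               class = "ncrus_no_resonance")
})

test_that("unit reporting round-trips losslessly", {
  vitis <- table3_vitis()
  s <- layer_transmission(vitis, frequencies = seq(3e5, 1e6, by = 2e3))
  fit <- fit_leaf_spectrum(s, fit_config(seed = 3))
  r <- report_units(fit)
  back <- leaf_layer_from_report(r$thickness_um, r$lma_g_m2, r$c33_mpa,
                                 r$alpha_np_m)
  expect_equal(back$thickness, fit$layer$thickness, tolerance = 1e-12)
  expect_equal(back$density, fit$layer$density, tolerance = 1e-12)
  # SI check of the reporting arithmetic
  l <- leaf_layer(1.74e-4, 1264.4, 231.9, 0)
  ru <- report_units(l)
  expect_equal(ru$thickness_um, 174, tolerance = 1e-9)
  expect_equal(ru$lma_g_m2, 1264.4 * 1.74e-4 * 1e3, tolerance = 1e-12)
  expect_equal(ru$alpha_np_m, 0)
})

test_that("fit configuration validates its inputs", {
  expect_error(fit_config(), "seed")
  expect_error(fit_config(seed = 1, bounds = list(thickness = c(1, 2))),
               "bounds")
  expect_error(fit_config(seed = 1,
                          bounds = list(thickness = c(2, 1),
                                        density = c(1, 2),
                                        velocity = c(1, 2),
                                        alpha_res = c(1, 2))),
               "increasing")
})
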