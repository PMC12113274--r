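# Closed-form model layer: scalar oracle values computed independently
# (plain arithmetic with RT/F at 295 K), plus shape/limit properties.

test_that("Boltzmann curve hits its midpoint, limits and tabulated values", {
  p <- boltzmann_params(1, v_half = 6, z = 1.6)
  expect_equal(boltzmann(6, p), 0.5)
  # RT/F = 25.42 mV at 295 K; x = 65*1.6/25.42 -> 1/(1+exp(-x)) = 0.98356
  expect_equal(boltzmann(71, p), 0.98356, tolerance = 1e-4)
  expect_equal(boltzmann(-1e4, p), 0, tolerance = 1e-12)
  expect_equal(boltzmann(1e4, p), 1, tolerance = 1e-12)
  expect_error(boltzmann(NaN, p), "finite")
})

test_that("Boltzmann is monotone, rising for activation, falling for inactivation", {
  v <- seq(-120, 60, by = 2)
  for (z in c(0.5, 1.6, 3.1)) {
    act <- boltzmann(v, boltzmann_params(1, -20, z, "activation"))
    inact <- boltzmann(v, boltzmann_params(1, -60, z, "inactivation"))
    expect_true(all(diff(act) > 0))
    expect_true(all(diff(inact) < 0))
  }
})

test_that("activation time course reduces to a single exponential at sigma 1", {
  f1 <- activation_fit(100, tau_act = 10, sigma = 1, t0_offset = 0)
  t <- seq(0, 80, by = 0.37)
  expect_equal(activation_timecourse(t, f1), 100 * (1 - exp(-t / 10)))
  expect_equal(activation_timecourse(10, f1), 100 * (1 - exp(-1)))
  # plateau
  expect_equal(activation_timecourse(1e5, f1), 100)
  # sigmoid case: 100*(1 - e^-1)^2 = 39.958
  f2 <- activation_fit(100, tau_act = 10, sigma = 2, t0_offset = 0)
  expect_equal(activation_timecourse(10, f2), 39.958, tolerance = 1e-4)
  expect_error(activation_fit(100, tau_act = -1), "positive")
})

test_that("bi-exponential relaxation: initial value, asymptote, oracle point", {
  f <- biexp_fit(y0 = 0, a1 = 80, tau1 = 16, a2 = 20, tau2 = 100, t0 = 0)
  expect_equal(biexp_relaxation(0, f), 100)
  expect_equal(biexp_relaxation(1e6, f), 0, tolerance = 1e-9)
  # 80*e^-1 + 20*e^-0.16 = 46.473
  expect_equal(biexp_relaxation(16, f), 46.473, tolerance = 1e-4)
  expect_error(biexp_relaxation(-1, f), "t0")
  expect_error(biexp_fit(a1 = 1, tau1 = 0), "positive")
})

test_that("biexp_fit stores components fast-first and encodes mono as a2 = 0", {
  f <- biexp_fit(a1 = 20, tau1 = 100, a2 = 80, tau2 = 16)
  expect_lt(f$tau1, f$tau2)
  expect_equal(f$a1, 80)
  mono <- biexp_fit(a1 = 50, tau1 = 30)
  t <- seq(0, 100, by = 1)
  expect_equal(biexp_relaxation(t, mono), 50 * exp(-t / 30))
})

test_that("equilibrium block: half at KD, none at zero, 98% at the pre-block dose", {
  m <- block_model(6)
  expect_equal(unblocked_fraction(6, m), 0.5)
  expect_equal(unblocked_fraction(0, m), 1)
  # 1 uM KD 6 nM pre-block convention: 0.35 uM leaves 6/356 = 1.69% -> 98% block
  expect_equal(unblocked_fraction(350, m), 6 / 356)
  expect_equal(round(100 * (1 - unblocked_fraction(350, m))), 98)
  conc <- 10^seq(-2, 6, by = 0.1)
  u <- unblocked_fraction(conc, m)
  expect_true(all(diff(u) < 0))
  expect_true(all(u > 0 & u <= 1))
  expect_error(unblocked_fraction(-1, m), ">= 0")
})

test_that("saturating voltage-sensor modulator returns its configured remainder", {
  m <- block_model(1, mechanism = "saturating_vsd_modulator",
                   remaining_fraction = 0.07)
  expect_equal(unblocked_fraction(100, m), 0.07)
  expect_equal(unblocked_fraction(0, m), 1)
})

test_that("Hill curve: midpoint, saturating floor, oracle point", {
  h <- hill_fit(ic50 = 5100, n_hill = 1, base = 0.01)
  expect_equal(hill_response(5100, h), (1 + 0.01) / 2)
  expect_equal(hill_response(1e12, h), 0.01, tolerance = 1e-6)
  # 0.01 + 0.99/(1 + 3500/5100) = 0.59709
  expect_equal(hill_response(3500, h), 0.59709, tolerance = 1e-4)
  expect_error(hill_fit(ic50 = -1), "ic50")
})

test_that("Nernst potential matches the recording-solution oracle", {
  expect_equal(nernst_potential(100, 100), 0)
  # K+: 130 mM in / 5 mM out at 295 K -> -82.8 mV
  expect_equal(nernst_potential(130, 5), -82.8, tolerance = 0.05)
  expect_equal(nernst_potential(130, 5, valence = 2),
               nernst_potential(130, 5) / 2)
  expect_error(nernst_potential(0, 5), "> 0")
  expect_equal(phys_constants(295)$rt_over_f_mV, 25.42, tolerance = 0.005)
})

test_that("a composite with a pre-blocked homomer tracks the pure heteromer Hill curve", {
  # homomer (KD 6 nM) weighted so it is <= 2% of the reference measurement
  # at 0.35 uM; after renormalization at 0.35 uM the composite deviates from
  # the pure heteromer curve by < 2% everywhere above the reference
  hom <- block_model(6)
  het <- block_model(5100)
  w_hom <- 0.2
  conc <- seq(350, 50000, by = 50)
  comp <- w_hom * unblocked_fraction(conc, hom) +
    (1 - w_hom) * unblocked_fraction(conc, het)
  comp <- comp / (w_hom * unblocked_fraction(350, hom) +
                    (1 - w_hom) * unblocked_fraction(350, het))
  pure <- unblocked_fraction(conc, het) / unblocked_fraction(350, het)
  expect_lt(w_hom * unblocked_fraction(350, hom) /
              (w_hom * unblocked_fraction(350, hom) +
                 (1 - w_hom) * unblocked_fraction(350, het)), 0.02)
  expect_lt(max(abs(comp - pure)), 0.02)
})
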