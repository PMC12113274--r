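# Fitter round trips on noise-free forward-model data, degenerate-input
# errors, noise robustness and scale equivariance.

test_that("activation fit recovers its own forward model", {
  t <- seq(0, 200, by = 0.05)
  mk_sweep <- function(i) {
    manual_sweep(t, i, data.frame(voltage = -9, duration = 200.05,
                                  role = "step"))
  }
  # single exponential: tau recovered within 1%
  i1 <- activation_timecourse(t, activation_fit(200, 10, 1, t0_offset = 0))
  f1 <- fit_activation(mk_sweep(i1), t0_offset = 0)
  expect_equal(f1$fit$tau_act, 10, tolerance = 0.01)
  expect_true(f1$diagnostics$converged)
  # sigmoid rise: all parameters within 2%
  i2 <- activation_timecourse(t, activation_fit(100, 8, 2.5, t0_offset = 0))
  f2 <- fit_activation(mk_sweep(i2), t0_offset = 0)
  expect_equal(f2$fit$amplitude, 100, tolerance = 0.02)
  expect_equal(f2$fit$tau_act, 8, tolerance = 0.02)
  expect_equal(f2$fit$sigma, 2.5, tolerance = 0.02)
  expect_error(fit_activation(mk_sweep(rep(0, length(t))), t0_offset = 0),
               "no rise")
})

test_that("Boltzmann fit recovers generator parameters on the standard grids", {
  v <- seq(-79, 71, by = 10)
  act <- boltzmann_params(1, 6, 1.6)
  pts <- data.frame(voltage = v, value = boltzmann(v, act))
  f <- fit_boltzmann(pts, "activation")
  expect_equal(f$fit$v_half, 6, tolerance = 0.1 / 6)
  expect_equal(f$fit$z, 1.6, tolerance = 0.01 / 1.6)
  # inactivation direction with min-max normalized input
  vh <- seq(-109, -19, by = 10)
  inact <- boltzmann_params(1, -66, 1.8, "inactivation")
  y <- boltzmann(vh, inact)
  y <- (y - min(y)) / (max(y) - min(y))
  fi <- fit_boltzmann(data.frame(voltage = vh, value = y), "inactivation",
                      minmax = TRUE)
  expect_equal(fi$fit$v_half, -66, tolerance = 0.1 / 66)
  expect_equal(fi$fit$z, 1.8, tolerance = 0.01)
  expect_error(fit_boltzmann(pts[1:2, ], "activation"), "insufficient")
  flat <- data.frame(voltage = v, value = rep(1, length(v)) + 1e-6 * v)
  ff <- fit_boltzmann(flat, "activation")
  expect_match(paste(ff$diagnostics$flags, collapse = " "),
               "non_identifiable")
})

test_that("deactivation fit recovers fast and slow components", {
  t <- seq(0, 300, by = 0.05)
  mk <- function(i) {
    manual_sweep(t, i, data.frame(voltage = -45, duration = 300.05,
                                  role = "tail"))
  }
  i <- biexp_relaxation(t, biexp_fit(y0 = 20, a1 = 80, tau1 = 16, a2 = 20,
                                     tau2 = 100))
  f <- fit_deactivation(mk(i))
  expect_equal(f$fit$tau1, 16, tolerance = 0.02)
  expect_equal(f$fit$tau2, 100, tolerance = 0.05)
  expect_lt(f$fit$tau1, f$fit$tau2)
  # monoexp mode on a pure single exponential: exact, a2 = 0
  im <- biexp_relaxation(t, biexp_fit(y0 = 5, a1 = 60, tau1 = 30))
  fm <- fit_deactivation(mk(im), mode = "monoexp")
  expect_equal(fm$fit$tau1, 30, tolerance = 1e-6)
  expect_equal(fm$fit$a2, 0)
  expect_error(fit_deactivation(mk(rep(50, length(t)))), "no relaxation")
})

test_that("fitted biexp components always come back fast-first", {
  t <- seq(0, 300, by = 0.1)
  set.seed(7)
  for (k in 1:5) {
    tau1 <- runif(1, 5, 30); tau2 <- tau1 * runif(1, 3, 10)
    a1 <- runif(1, 40, 120); a2 <- runif(1, 10, 60)
    i <- biexp_relaxation(t, biexp_fit(y0 = 0, a1 = a1, tau1 = tau1,
                                       a2 = a2, tau2 = tau2))
    f <- fit_deactivation(manual_sweep(t, i,
                                       data.frame(voltage = -45,
                                                  duration = 300.1,
                                                  role = "tail")))
    expect_lt(f$fit$tau1, f$fit$tau2)
    expect_equal(f$fit$tau1, tau1, tolerance = 0.02)
  }
})

test_that("Hill fit recovers IC50 on the standard ladder, fixed or free nH", {
  concs <- c(350, 1100, 3500, 11000, 35000)
  truth <- hill_fit(5100, 1, 0.01)
  resp <- hill_response(concs, truth)
  f <- fit_hill(concs, resp, fix_n_hill = 1)
  expect_equal(f$fit$ic50, 5100, tolerance = 0.02)
  expect_equal(f$fit$base, 0.01, tolerance = 0.1)
  ff <- fit_hill(concs, resp, fix_n_hill = NULL)
  expect_equal(ff$fit$n_hill, 1, tolerance = 0.02)
  # reference-normalized data with the matching model
  ref_resp <- resp / hill_response(350, truth)
  fr <- fit_hill(concs, ref_resp, fix_n_hill = 1, reference_conc = 350)
  expect_equal(fr$fit$ic50, 5100, tolerance = 0.001)
  expect_error(fit_hill(c(100, 1000), c(1, 0.5)), "3 distinct")
  flat <- fit_hill(concs, rep(1, 5))
  expect_match(paste(flat$diagnostics$flags, collapse = " "),
               "non_identifiable")
})

test_that("fits are robust to 2% amplitude noise", {
  t <- seq(0, 300, by = 0.05)
  set.seed(123)
  taus <- replicate(100, {
    i <- biexp_relaxation(t, biexp_fit(y0 = 10, a1 = 80, tau1 = 16, a2 = 20,
                                       tau2 = 100)) + rnorm(length(t), 0, 2)
    f <- fit_deactivation(manual_sweep(t, i,
                                       data.frame(voltage = -45,
                                                  duration = 300.05,
                                                  role = "tail")))
    f$fit$tau1
  })
  expect_lt(abs(stats::median(taus) / 16 - 1), 0.05)
})

test_that("scaling all currents rescales amplitudes but no shape parameter", {
  t <- seq(0, 200, by = 0.05)
  i <- activation_timecourse(t, activation_fit(100, 8, 2.5, t0_offset = 0))
  ep <- data.frame(voltage = -9, duration = 200.05, role = "step")
  a1 <- fit_activation(manual_sweep(t, i, ep), t0_offset = 0)
  a2 <- fit_activation(manual_sweep(t, 3.7 * i, ep), t0_offset = 0)
  expect_equal(a2$fit$tau_act, a1$fit$tau_act, tolerance = 1e-6)
  expect_equal(a2$fit$sigma, a1$fit$sigma, tolerance = 1e-6)
  expect_equal(a2$fit$amplitude, 3.7 * a1$fit$amplitude, tolerance = 1e-6)

  v <- seq(-79, 71, by = 10)
  y <- boltzmann(v, boltzmann_params(1, 6, 1.6))
  b1 <- fit_boltzmann(data.frame(voltage = v, value = y))
  b2 <- fit_boltzmann(data.frame(voltage = v, value = 5 * y))
  expect_equal(b2$fit$v_half, b1$fit$v_half, tolerance = 1e-6)
  expect_equal(b2$fit$z, b1$fit$z, tolerance = 1e-6)
  expect_equal(b2$fit$amplitude, 5 * b1$fit$amplitude, tolerance = 1e-6)

  tt <- seq(0, 300, by = 0.05)
  d <- biexp_relaxation(tt, biexp_fit(y0 = 10, a1 = 80, tau1 = 16, a2 = 20,
                                      tau2 = 100))
  epd <- data.frame(voltage = -45, duration = 300.05, role = "tail")
  d1 <- fit_deactivation(manual_sweep(tt, d, epd))
  d2 <- fit_deactivation(manual_sweep(tt, 0.2 * d, epd))
  expect_equal(d2$fit$tau1, d1$fit$tau1, tolerance = 1e-6)
  expect_equal(d2$fit$a1, 0.2 * d1$fit$a1, tolerance = 1e-5)
})

test_that("summaries use arithmetic or geometric means as requested", {
  expect_equal(summarize_values(c(10, 10, 10), "log")$estimate, 10)
  expect_equal(summarize_values(c(1, 100), "log")$estimate, 10)
  lin <- summarize_values(c(1, 2, 3), "linear")
  expect_equal(lin$estimate, 2)
  expect_equal(lin$sem, stats::sd(c(1, 2, 3)) / sqrt(3))
  expect_error(summarize_values(c(1, -1), "log"), "positive")
  set.seed(99)
  x <- exp(rnorm(1000, log(16), 0.5))  # lognormal, median 16
  expect_equal(summarize_values(x, "log")$estimate, 16, tolerance = 0.03)
})
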