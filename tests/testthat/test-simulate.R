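# Sweep generator: leak linearity, block consistency, determinism,
# superposition, tail continuity, rundown and P/4 behavior.

test_that("protocol presets carry the expected structure and reject bad input", {
  p <- build_protocol("cho_dose_response")
  expect_equal(p$holding, -89)
  expect_equal(p$epochs$voltage, c(71, -9))
  expect_equal(p$epochs$duration, c(200, 300))
  expect_equal(p$inter_sweep_interval, 5)
  expect_equal(p$ljp, -9)
  d <- build_protocol("drg_tail")
  expect_equal(d$epochs$voltage, c(6, -44))
  fam <- build_protocol("cho_activation_family")
  expect_equal(fam$step_voltages, seq(-79, 71, by = 10))
  expect_error(build_protocol("no_such_protocol"), "unknown")
  expect_error(build_protocol(epochs = data.frame(voltage = 0, duration = 0,
                                                  role = "step"),
                              holding = -80),
               "positive")
})

test_that("a channel-free cell produces a pure ohmic leak trace", {
  cell <- cell_model(list(), leak_conductance = 2, leak_reversal = -70)
  sw <- simulate_sweep(cell, step_tail_protocol(), noise = FALSE)
  expect_equal(sw$current, 2 * (sw$voltage - -70))
})

test_that("steady-state block ratio equals the analytic unblocked fraction", {
  cell <- cell_model(list(simple_pop()))
  proto <- step_tail_protocol(step_v = 5, dt = 0.1)
  base <- simulate_sweep(cell, proto, "baseline", sweep_index = 3)
  ry <- simulate_sweep(cell, proto, "ry785", sweep_index = 3)
  late <- base$time > 180 & base$time < 220  # end of step epoch
  expect_equal(ry$current[late] / base$current[late],
               rep(6 / 1006, sum(late)), tolerance = 1e-12)
  # 0.6% of baseline at 1 uM for a homomer-only cell
  expect_equal(mean(ry$current[late] / base$current[late]), 0.00596,
               tolerance = 1e-3)
})

test_that("identical cells and seeds give bit-identical sweeps", {
  mk <- function() {
    cell <- cell_model(list(simple_pop()), noise_sd = 5, seed = 42L)
    simulate_sweep(cell, step_tail_protocol(), sweep_index = 2)
  }
  a <- mk(); b <- mk()
  expect_identical(a$current, b$current)
  cell <- cell_model(list(simple_pop()), noise_sd = 5, seed = 42L)
  c2 <- simulate_sweep(cell, step_tail_protocol(), sweep_index = 3)
  expect_false(identical(a$current, c2$current))
})

test_that("noise-free currents superpose across populations", {
  p1 <- simple_pop("a", gmax = 4, v_half = -10)
  p2 <- simple_pop("b", gmax = 7, v_half = 10,
                   deact_tab = data.frame(voltage = -45, tau_fast = 40,
                                          tau_slow = 150, frac_fast = 0.7))
  proto <- step_tail_protocol()
  both <- simulate_sweep(cell_model(list(p1, p2)), proto, noise = FALSE)
  one <- simulate_sweep(cell_model(list(p1)), proto, noise = FALSE)
  two <- simulate_sweep(cell_model(list(p2)), proto, noise = FALSE)
  expect_equal(both$current, one$current + two$current, tolerance = 1e-12)
})

test_that("conductance is continuous across the step-to-tail boundary", {
  cell <- cell_model(list(simple_pop()))
  proto <- step_tail_protocol(dt = 0.01)
  sw <- simulate_sweep(cell, proto, noise = FALSE)
  ek <- -90
  g <- sw$current / (sw$voltage - ek)
  boundary <- which(diff(sw$voltage) != 0)
  for (b in boundary[-1]) {  # skip holding->step (start from near-zero g)
    expect_lt(abs(g[b + 1] - g[b]), 0.02 * max(abs(g)) + 1e-9)
  }
})

test_that("rundown declines geometrically to its floor and can be disabled", {
  off <- cell_model(list(simple_pop()))
  expect_equal(apply_rundown(off, 0:50), rep(1, 51))
  cell <- cell_model(list(simple_pop()),
                     rundown = list(rate = 0.0104, floor = 0.5))
  s <- apply_rundown(cell, 0:300)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 0.5))
  expect_equal(min(s), 0.5)
  # the wash-schedule calibration: ~30% loss by the end of a 35-sweep series
  expect_equal(apply_rundown(cell, 34), 0.70, tolerance = 0.005)
  expect_error(apply_rundown(cell, -1), ">= 0")
})

test_that("P/4 correction removes linear leak exactly and spares channel current", {
  proto <- build_protocol(epochs = data.frame(voltage = -9, duration = 200,
                                              role = "step"),
                          holding = -89, sample_interval = 0.1)
  leak_only <- cell_model(list(), leak_conductance = 3, leak_reversal = -40)
  main <- simulate_sweep(leak_only, proto, noise = FALSE)
  subs <- p4_sub_sweeps(leak_only, proto, noise = FALSE)
  corrected <- p4_subtract(main, subs$sub_sweeps)
  expect_equal(corrected$current, rep(0, length(main$current)),
               tolerance = 1e-10)
  expect_true(corrected$p4_subtracted)

  # channel + leak: correction recovers the channel-only simulation
  pop <- simple_pop(v_half = -5, act_tab = data.frame(voltage = -9, tau = 10,
                                                      sigma = 2))
  mixed <- cell_model(list(pop), leak_conductance = 3, leak_reversal = -40)
  channel_only <- cell_model(list(pop))
  main2 <- simulate_sweep(mixed, proto, noise = FALSE)
  subs2 <- p4_sub_sweeps(mixed, proto, noise = FALSE)
  corrected2 <- p4_subtract(main2, subs2$sub_sweeps)
  ref <- simulate_sweep(channel_only, proto, noise = FALSE)
  expect_equal(corrected2$current, ref$current,
               tolerance = 0.01 * max(abs(ref$current)))
  expect_error(p4_subtract(main2, subs2$sub_sweeps[1:3]), "4 sub-sweeps")
  two_step <- step_tail_protocol()
  expect_error(p4_sub_sweeps(mixed, two_step), "single non-holding")
})

test_that("P/4 subtraction combines noise from main and sub-sweeps as expected", {
  proto <- build_protocol(epochs = data.frame(voltage = -9, duration = 400,
                                              role = "step"),
                          holding = -89, sample_interval = 0.1,
                          pre_hold_ms = 400)
  cell <- cell_model(list(), leak_conductance = 3, leak_reversal = -40,
                     noise_sd = 4, seed = 11L)
  main <- simulate_sweep(cell, proto)
  subs <- p4_sub_sweeps(cell, proto)
  corrected <- p4_subtract(main, subs$sub_sweeps)
  # main + 4 independent sub-sweeps -> ~5x the per-sweep variance
  expect_equal(stats::var(corrected$current), 5 * 4^2, tolerance = 0.15)
})
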