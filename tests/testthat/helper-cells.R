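# Small cells and protocols used across tests. Coarse sampling keeps the
# suite fast; physics is identical to the full-resolution presets.

const_295 <- phys_constants(295)

simple_pop <- function(name = "kv2", gmax = 10, v_half = -10, z = 2,
                       act_tab = data.frame(voltage = 0, tau = 5, sigma = 2),
                       deact_tab = data.frame(voltage = -45, tau_fast = 16,
                                              tau_slow = 100,
                                              frac_fast = 0.8),
                       ry785 = block_model(6), gxtx_remaining = 0,
                       inactivation = NULL, inact_floor = 1,
                       reversal = -90) {
  population_spec(name = name, gmax = gmax,
                  activation = boltzmann_params(1, v_half, z, "activation"),
                  act_kinetics = act_tab, deact_kinetics = deact_tab,
                  inactivation = inactivation, inact_floor = inact_floor,
                  ry785 = ry785, gxtx_remaining = gxtx_remaining,
                  reversal = reversal)
}

step_tail_protocol <- function(step_v = 5, tail_v = -45, holding = -74,
                               dt = 0.1, step_ms = 200, tail_ms = 300) {
  build_protocol(epochs = data.frame(voltage = c(step_v, tail_v),
                                     duration = c(step_ms, tail_ms),
                                     role = c("step", "tail")),
                 holding = holding, sample_interval = dt)
}

# bare sweep object from explicit vectors (for window-measure tests)
manual_sweep <- function(t, i, epochs) {
  epochs$start <- cumsum(c(0, epochs$duration[-nrow(epochs)]))
  epochs$end <- epochs$start + epochs$duration
  structure(list(sweep_id = "manual", condition = "baseline",
                 conc_ry785 = 0, conc_gxtx = 0, step_voltage = NA_real_,
                 sweep_index = 0L, time = t,
                 voltage = epochs$voltage[findInterval(t, epochs$start)],
                 current = i, p4_subtracted = FALSE, epochs = epochs),
            class = "kvs_sweep")
}
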