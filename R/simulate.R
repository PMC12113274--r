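# Forward simulation of whole-cell voltage-clamp sweeps. Channel open
# probability follows the power-exponential rise toward the Boltzmann steady
# state during activating epochs and relaxes bi-exponentially during
# deactivating epochs; slow inactivation engages only in conditioning epochs
# of a second or longer. Drug block is an instantaneous equilibrium scale.

.CONDITIONS <- c("baseline", "ry785", "ry785_gxtx", "vehicle")

# epochs >= this long engage the slow inactivation gate
.INACT_ENGAGE_MS <- 1000

.condition_concs <- function(condition) {
  switch(condition,
         baseline = c(ry785 = 0, gxtx = 0),
         vehicle = c(ry785 = 0, gxtx = 0),
         ry785 = c(ry785 = 1000, gxtx = 0),
         ry785_gxtx = c(ry785 = 1000, gxtx = 100),
         stop("unknown condition: ", condition))
}

# drug scale for one population under given concentrations (nM)
.block_scale <- function(pop, conc_ry785, conc_gxtx) {
  s <- 1
  if (!is.null(pop$ry785) && conc_ry785 > 0) {
    s <- s * unblocked_fraction(conc_ry785, pop$ry785)
  }
  if (conc_gxtx > 0) s <- s * pop$gxtx_remaining
  s
}

# open-probability (activation * availability) trace for one population
# across the epoch table; returns vector over all samples
.population_po <- function(pop, ep, t, dt, const) {
  n <- length(t)
  po <- numeric(n)
  a <- boltzmann(ep$voltage[1], pop$activation, const)  # steady at holding
  h <- .avail_inf(pop, ep$voltage[1], const)
  for (k in seq_len(nrow(ep))) {
    sel <- t >= ep$start[k] & t < ep$end[k]
    if (!any(sel)) next
    tl <- t[sel] - ep$start[k]
    v <- ep$voltage[k]
    a_inf <- boltzmann(v, pop$activation, const)
    if (a_inf >= a) {
      kin <- act_kinetics_at(pop, v)
      a_t <- a + (a_inf - a) * (1 - exp(-tl / kin$tau))^kin$sigma
      a_end <- a + (a_inf - a) *
        (1 - exp(-ep$duration[k] / kin$tau))^kin$sigma
    } else {
      kin <- deact_kinetics_at(pop, v)
      relax <- kin$frac_fast * exp(-tl / kin$tau_fast) +
        (1 - kin$frac_fast) * exp(-tl / kin$tau_slow)
      a_t <- a_inf + (a - a_inf) * relax
      a_end <- a_inf + (a - a_inf) *
        (kin$frac_fast * exp(-ep$duration[k] / kin$tau_fast) +
           (1 - kin$frac_fast) * exp(-ep$duration[k] / kin$tau_slow))
    }
    if (!is.null(pop$inactivation) && ep$duration[k] >= .INACT_ENGAGE_MS) {
      h_inf <- .avail_inf(pop, v, const)
      h_t <- h_inf + (h - h_inf) * exp(-tl / pop$tau_inact)
      h_end <- h_inf + (h - h_inf) * exp(-ep$duration[k] / pop$tau_inact)
    } else {
      h_t <- h
      h_end <- h
    }
    po[sel] <- a_t * h_t
    a <- a_end
    h <- h_end
  }
  po
}

#' Simulate one voltage-clamp sweep
#'
#' Total current is the sum over populations of
#' `gmax * rundown(sweep_index) * block(condition) * Po(V, t) * (V - E_rev)`
#' plus ohmic leak and (optionally) seeded Gaussian noise.
#'
#' @param cell A [cell_model()].
#' @param protocol A [build_protocol()] object.
#' @param condition One of `"baseline"`, `"ry785"`, `"ry785_gxtx"`,
#'   `"vehicle"`.
#' @param sweep_index Zero-based index into the recording schedule (drives
#'   rundown and the per-sweep noise stream).
#' @param step_voltage Optional voltage substituted into the protocol's
#'   varied epoch.
#' @param conc_ry785,conc_gxtx Optional concentration overrides (nM);
#'   defaults follow the condition (1 uM RY785, 100 nM GxTX).
#' @param noise Apply Gaussian noise (if the cell has `noise_sd > 0`)?
#' @return A `kvs_sweep` object: time (ms), command voltage (mV), current
#'   (pA) vectors plus condition metadata and the epoch table.
#' @export
simulate_sweep <- function(cell, protocol, condition = "baseline",
                           sweep_index = 0, step_voltage = NULL,
                           conc_ry785 = NULL, conc_gxtx = NULL,
                           noise = TRUE) {
  stopifnot(inherits(cell, "cell_model"),
            inherits(protocol, "voltage_protocol"))
  condition <- match.arg(condition, .CONDITIONS)
  concs <- .condition_concs(condition)
  if (is.null(conc_ry785)) conc_ry785 <- unname(concs["ry785"])
  if (is.null(conc_gxtx)) conc_gxtx <- unname(concs["gxtx"])

  ep <- .sweep_epochs(protocol, step_voltage)
  dt <- protocol$sample_interval
  total <- sum(ep$duration)
  t <- seq(0, total - dt / 2, by = dt)
  v <- ep$voltage[findInterval(t, ep$start)]

  run <- apply_rundown(cell, sweep_index)
  current <- cell$leak_conductance * (v - cell$leak_reversal)
  for (pop in cell$populations) {
    if (pop$gmax == 0) next
    scale <- pop$gmax * run * .block_scale(pop, conc_ry785, conc_gxtx)
    if (scale == 0) next
    po <- .population_po(pop, ep, t, dt, cell$const)
    current <- current + scale * po * (v - pop$reversal)
  }
  if (noise && cell$noise_sd > 0) {
    current <- current +
      .seeded_noise(cell, sweep_index, condition, step_voltage, length(t))
  }
  sv <- if (is.null(step_voltage)) {
    ep$voltage[ep$role == protocol$vary_role][1]
  } else {
    step_voltage
  }
  structure(
    list(sweep_id = sprintf("%s_%s_sw%03d_v%+.0f", cell$id, condition,
                            sweep_index, sv),
         condition = condition, conc_ry785 = conc_ry785,
         conc_gxtx = conc_gxtx, step_voltage = sv,
         sweep_index = sweep_index, time = t, voltage = v,
         current = current, p4_subtracted = FALSE, epochs = ep),
    class = "kvs_sweep")
}

# reproducible per-sweep Gaussian noise; leaves the caller's RNG untouched
.seeded_noise <- function(cell, sweep_index, condition, step_voltage, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  sv <- if (is.null(step_voltage)) 0 else round(step_voltage)
  s <- (abs(cell$seed) * 1000003 + sweep_index * 8191 +
          match(condition, .CONDITIONS) * 131 + (sv + 500)) %%
    2147483647L
  set.seed(as.integer(s))
  stats::rnorm(n, 0, cell$noise_sd)
}

#' Simulate a multi-condition recording
#'
#' Runs the protocol (or protocol family, when it has `step_voltages`) under
#' each condition in order. Sweep indices advance sequentially through the
#' whole schedule unless `shared_indices = TRUE`, in which case they restart
#' at 0 for each condition so that matched sweeps share rundown state.
#'
#' @inheritParams simulate_sweep
#' @param conditions Character vector of conditions, applied in order.
#' @param shared_indices Restart sweep indices per condition?
#' @param preset Optional preset name recorded in the metadata.
#' @return A `kvs_recording`: metadata plus a list of `kvs_sweep`s, one per
#'   (condition, step voltage) pair.
#' @export
simulate_recording <- function(cell, protocol,
                               conditions = c("baseline", "ry785",
                                              "ry785_gxtx"),
                               noise = TRUE, shared_indices = FALSE,
                               preset = NA_character_) {
  stopifnot(inherits(cell, "cell_model"),
            inherits(protocol, "voltage_protocol"))
  svs <- protocol$step_voltages
  if (is.null(svs)) svs <- NA_real_
  sweeps <- list()
  idx <- 0L
  for (cond in conditions) {
    if (shared_indices) idx <- 0L
    for (sv in svs) {
      sweeps[[length(sweeps) + 1L]] <- simulate_sweep(
        cell, protocol, condition = cond, sweep_index = idx,
        step_voltage = if (is.na(sv)) NULL else sv, noise = noise)
      idx <- idx + 1L
    }
  }
  structure(
    list(metadata = list(cell_id = cell$id, preset = preset,
                         seed = cell$seed, protocol = protocol$name,
                         ljp = protocol$ljp,
                         sample_interval = protocol$sample_interval,
                         conditions = conditions),
         sweeps = sweeps),
    class = "kvs_recording")
}

#' Simulate an RY785 concentration-effect series
#'
#' Repeats the protocol at each concentration of the ladder (several sweeps
#' per concentration, as in a perfusion experiment); rundown and noise apply
#' if the cell has them enabled. A vehicle arm repeats the reference
#' concentration through the same schedule instead.
#'
#' @inheritParams simulate_sweep
#' @param concs_nM Concentration ladder (nM), low to high.
#' @param sweeps_per_conc Sweeps recorded at each concentration.
#' @param vehicle If `TRUE`, every stage uses `concs_nM[1]` (time-matched
#'   solution-exchange control).
#' @return A `kvs_recording` whose sweeps are tagged with `conc_ry785`.
#' @export
simulate_dose_response <- function(cell, protocol, concs_nM,
                                   sweeps_per_conc = 7, noise = TRUE,
                                   vehicle = FALSE) {
  stopifnot(length(concs_nM) >= 1, all(concs_nM >= 0))
  sweeps <- list()
  idx <- 0L
  for (conc in concs_nM) {
    use <- if (vehicle) concs_nM[1] else conc
    for (i in seq_len(sweeps_per_conc)) {
      sw <- simulate_sweep(cell, protocol,
                           condition = if (vehicle) "vehicle" else "ry785",
                           sweep_index = idx, conc_ry785 = use,
                           noise = noise)
      sw$conc_stage <- conc  # ladder stage label (vehicle arm keeps schedule)
      sweeps[[length(sweeps) + 1L]] <- sw
      idx <- idx + 1L
    }
  }
  structure(
    list(metadata = list(cell_id = cell$id, preset = NA_character_,
                         seed = cell$seed, protocol = protocol$name,
                         ljp = protocol$ljp,
                         sample_interval = protocol$sample_interval,
                         conditions = if (vehicle) "vehicle" else "ry785"),
         sweeps = sweeps),
    class = "kvs_recording")
}

#' Generate P/4 leak-subtraction sub-sweeps
#'
#' Emits four quarter-amplitude pulses from the holding potential mirroring
#' the protocol's single main step, plus the combined correction trace (the
#' summed baseline-subtracted sub-sweep currents). Subtracting the correction
#' from the main sweep removes linear (ohmic) leak exactly in the noise-free
#' case; see [p4_subtract()].
#'
#' @inheritParams simulate_sweep
#' @return List with `sub_sweeps` (four `kvs_sweep`s), `correction` (pA
#'   vector on the main sweep's time base) and `scale` (always 1 for exact
#'   quarter pulses).
#' @export
p4_sub_sweeps <- function(cell, protocol, condition = "baseline",
                          sweep_index = 0, noise = TRUE) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  ep <- protocol$epochs
  active <- which(ep$voltage != protocol$holding)
  if (length(active) != 1L) {
    stop("P/4 generation supports protocols with a single non-holding epoch")
  }
  dv <- ep$voltage[active] - protocol$holding
  sub_proto <- protocol
  sub_proto$epochs$voltage[active] <- protocol$holding + dv / 4
  sub_proto$step_voltages <- NULL
  subs <- lapply(1:4, function(i) {
    simulate_sweep(cell, sub_proto, condition = condition,
                   sweep_index = sweep_index * 10L + i, noise = noise)
  })
  pre <- subs[[1]]$epochs$end[1]
  correction <- Reduce(`+`, lapply(subs, function(s) {
    s$current - mean(s$current[s$time < pre])
  }))
  list(sub_sweeps = subs, correction = correction, scale = 1)
}
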