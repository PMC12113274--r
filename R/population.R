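# One channel population: maximal conductance, activation Boltzmann,
# per-voltage activation/deactivation kinetics, optional slow inactivation,
# and drug sensitivities. A cell is a weighted set of these plus ohmic leak.

#' Specify one channel population
#'
#' @param name Population label (e.g. `"kv2_homomer"`).
#' @param gmax Maximal conductance (nS), >= 0.
#' @param activation [boltzmann_params()] for the conductance-voltage curve
#'   (activation direction).
#' @param act_kinetics Data frame with columns `voltage`, `tau`, `sigma`:
#'   activation time-course parameters tabulated at specific voltages. Time
#'   constants are interpolated log-linearly between tabulated voltages,
#'   sigmoidicity linearly; outside the table the nearest entry is used.
#' @param deact_kinetics Data frame with columns `voltage`, `tau_fast`,
#'   `tau_slow`, `frac_fast`: bi-exponential deactivation parameters, same
#'   interpolation rules. `frac_fast` is the fractional amplitude of the fast
#'   component (1 encodes mono-exponential deactivation).
#' @param inactivation Optional [boltzmann_params()] (inactivation direction)
#'   describing steady-state availability; `NULL` for non-inactivating
#'   populations.
#' @param inact_floor Residual availability at strongly inactivating
#'   voltages, in (0, 1]; steady-state availability is
#'   `floor + (1 - floor) * boltzmann(V)`.
#' @param tau_inact Time constant (ms) of the approach to steady-state
#'   availability; only long conditioning epochs (>= 1 s) engage it.
#' @param ry785 [block_model()] for RY785 sensitivity, or `NULL` if the
#'   population is RY785-insensitive.
#' @param gxtx_remaining Fraction of conductance remaining in 100 nM GxTX
#'   (0 for fully GxTX-sensitive populations, 1 for insensitive ones).
#' @param reversal Reversal potential of the conducted current (mV).
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, gmax, activation, act_kinetics,
                            deact_kinetics, inactivation = NULL,
                            inact_floor = 1, tau_inact = 2000,
                            ry785 = NULL, gxtx_remaining = 0,
                            reversal = -83) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(gmax), gmax >= 0,
            inherits(activation, "boltzmann_params"),
            activation$direction == "activation",
            is.data.frame(act_kinetics),
            all(c("voltage", "tau", "sigma") %in% names(act_kinetics)),
            nrow(act_kinetics) >= 1L,
            is.data.frame(deact_kinetics),
            all(c("voltage", "tau_fast", "tau_slow", "frac_fast") %in%
                  names(deact_kinetics)),
            nrow(deact_kinetics) >= 1L)
  if (any(act_kinetics$tau <= 0) || any(act_kinetics$sigma <= 0)) {
    stop("activation kinetics require positive tau and sigma")
  }
  if (any(deact_kinetics$tau_fast <= 0) || any(deact_kinetics$tau_slow <= 0)) {
    stop("deactivation kinetics require positive time constants")
  }
  if (any(deact_kinetics$frac_fast < 0 | deact_kinetics$frac_fast > 1)) {
    stop("frac_fast must be in [0, 1]")
  }
  if (!is.null(inactivation)) {
    stopifnot(inherits(inactivation, "boltzmann_params"),
              inactivation$direction == "inactivation")
    if (inact_floor <= 0 || inact_floor > 1) {
      stop("inact_floor must be in (0, 1]")
    }
    if (tau_inact <= 0) stop("tau_inact must be positive")
  }
  if (!is.null(ry785)) stopifnot(inherits(ry785, "block_model"))
  if (gxtx_remaining < 0 || gxtx_remaining > 1) {
    stop("gxtx_remaining must be in [0, 1]")
  }
  structure(
    list(name = name, gmax = gmax, activation = activation,
         act_kinetics = act_kinetics[order(act_kinetics$voltage), ,
                                     drop = FALSE],
         deact_kinetics = deact_kinetics[order(deact_kinetics$voltage), ,
                                         drop = FALSE],
         inactivation = inactivation, inact_floor = inact_floor,
         tau_inact = tau_inact, ry785 = ry785,
         gxtx_remaining = gxtx_remaining, reversal = reversal),
    class = "population_spec")
}

# interpolate one kinetics column at voltage v; taus in log space
.interp_kin <- function(tab, v, col, log_space = TRUE) {
  x <- tab$voltage
  y <- tab[[col]]
  if (length(x) == 1L) return(y)
  if (v <= min(x)) return(y[which.min(x)])
  if (v >= max(x)) return(y[which.max(x)])
  if (log_space) {
    exp(stats::approx(x, log(y), xout = v)$y)
  } else {
    stats::approx(x, y, xout = v)$y
  }
}

#' Activation kinetics of a population at a voltage
#'
#' @param pop A [population_spec()].
#' @param v Voltage (mV).
#' @return List with `tau` (ms) and `sigma`.
#' @export
act_kinetics_at <- function(pop, v) {
  stopifnot(inherits(pop, "population_spec"))
  list(tau = .interp_kin(pop$act_kinetics, v, "tau", TRUE),
       sigma = .interp_kin(pop$act_kinetics, v, "sigma", FALSE))
}

#' Deactivation kinetics of a population at a voltage
#'
#' @inheritParams act_kinetics_at
#' @return List with `tau_fast`, `tau_slow` (ms) and `frac_fast`.
#' @export
deact_kinetics_at <- function(pop, v) {
  stopifnot(inherits(pop, "population_spec"))
  list(tau_fast = .interp_kin(pop$deact_kinetics, v, "tau_fast", TRUE),
       tau_slow = .interp_kin(pop$deact_kinetics, v, "tau_slow", TRUE),
       frac_fast = .interp_kin(pop$deact_kinetics, v, "frac_fast", FALSE))
}

# steady-state availability of a population at voltage v
.avail_inf <- function(pop, v, const) {
  if (is.null(pop$inactivation)) return(rep(1, length(v)))
  pop$inact_floor + (1 - pop$inact_floor) * boltzmann(v, pop$inactivation,
                                                      const)
}

#' Specify a model cell
#'
#' @param populations List of [population_spec()] objects (may be empty for a
#'   leak-only cell).
#' @param leak_conductance Ohmic leak conductance (nS), >= 0.
#' @param leak_reversal Leak reversal potential (mV).
#' @param noise_sd Additive Gaussian noise SD per sample (pA), >= 0.
#' @param rundown List with `rate` (fractional amplitude loss per sweep) and
#'   `floor` (minimum scale, in (0, 1]); rundown multiplies channel
#'   conductances only, never leak.
#' @param seed Integer RNG seed; required whenever `noise_sd > 0`.
#' @param temperature_K Recording temperature (K).
#' @param id Cell identifier string.
#' @return A `cell_model` list.
#' @export
cell_model <- function(populations, leak_conductance = 0, leak_reversal = -74,
                       noise_sd = 0, rundown = list(rate = 0, floor = 1),
                       seed = NULL, temperature_K = 295, id = "cell") {
  stopifnot(is.list(populations),
            all(vapply(populations, inherits, TRUE, "population_spec")),
            leak_conductance >= 0, noise_sd >= 0)
  if (is.null(rundown$rate)) rundown$rate <- 0
  if (is.null(rundown$floor)) rundown$floor <- 1
  if (rundown$rate < 0 || rundown$rate >= 1) {
    stop("rundown rate must be in [0, 1)")
  }
  if (rundown$floor <= 0 || rundown$floor > 1) {
    stop("rundown floor must be in (0, 1]")
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required when noise_sd > 0")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  names(populations) <- vapply(populations, `[[`, "", "name")
  structure(
    list(populations = populations, leak_conductance = leak_conductance,
         leak_reversal = leak_reversal, noise_sd = noise_sd,
         rundown = rundown, seed = seed,
         const = phys_constants(temperature_K), id = id),
    class = "cell_model")
}

#' Multiplicative rundown scale at a sweep index
#'
#' Geometric decline `(1 - rate)^sweep_index`, clamped at the configured
#' floor; rundown affects channel conductances only.
#'
#' @param cell A [cell_model()].
#' @param sweep_index Zero-based sweep index (vectorised).
#' @return Scale factor(s) in `(0, 1]`, monotonically non-increasing.
#' @export
apply_rundown <- function(cell, sweep_index) {
  stopifnot(inherits(cell, "cell_model"))
  if (any(sweep_index < 0)) stop("sweep_index must be >= 0")
  pmax(cell$rundown$floor, (1 - cell$rundown$rate)^sweep_index)
}
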