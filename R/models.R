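# Closed-form gating and drug-block models shared by the sweep generator and
# the fitters: Boltzmann conductance-voltage curves, power-exponential
# activation, bi-exponential relaxation, equilibrium pore block, the Hill
# concentration-effect model, and the Nernst potential.

#' Physical constants for Boltzmann and Nernst calculations
#'
#' @param temperature_K Absolute temperature in kelvin. Recordings this
#'   package emulates were made at 295 K, so that is the default.
#' @return A list with Faraday's constant `F` (C/mol), the gas constant `R`
#'   (J/(mol K)), the temperature `T` (K) and the derived thermal voltage
#'   `rt_over_f_mV` (about 25.4 mV at 295 K).
#' @export
phys_constants <- function(temperature_K = 295) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("temperature_K must be a single positive number")
  }
  F_const <- 96485.33212
  R_const <- 8.314462618
  structure(
    list(F = F_const, R = R_const, T = temperature_K,
         rt_over_f_mV = 1000 * R_const * temperature_K / F_const),
    class = "phys_constants")
}

#' Boltzmann curve parameters
#'
#' @param amplitude Curve amplitude `A` (dimensionless for normalized
#'   conductance, or nS/pA for raw data).
#' @param v_half Half-maximal voltage (mV).
#' @param z Effective gating charge (elementary charges).
#' @param direction `"activation"` (curve increases with voltage) or
#'   `"inactivation"` (curve decreases with voltage).
#' @return A `boltzmann_params` list.
#' @export
boltzmann_params <- function(amplitude = 1, v_half, z,
                             direction = c("activation", "inactivation")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0,
            is.numeric(v_half), length(v_half) == 1L, is.finite(v_half),
            is.numeric(z), length(z) == 1L, z > 0)
  structure(list(amplitude = amplitude, v_half = v_half, z = z,
                 direction = direction),
            class = "boltzmann_params")
}

#' Evaluate a Boltzmann conductance-voltage curve
#'
#' `A * (1 + exp(-(V - V1/2) * z * F / (R * T)))^-1` for the activation
#' direction; the inactivation direction negates the exponent argument so the
#' curve decreases with voltage.
#'
#' @param v Membrane voltage(s), mV.
#' @param p A [boltzmann_params()] object.
#' @param const A [phys_constants()] object.
#' @return Curve value(s), same length as `v`.
#' @export
boltzmann <- function(v, p, const = phys_constants()) {
  stopifnot(inherits(p, "boltzmann_params"))
  if (any(!is.finite(v))) stop("voltage must be finite")
  x <- (v - p$v_half) * p$z / const$rt_over_f_mV
  if (p$direction == "inactivation") x <- -x
  p$amplitude / (1 + exp(-x))
}

#' Activation time-course parameters (power of an exponential)
#'
#' @param amplitude Plateau current `A` (pA).
#' @param tau_act Activation time constant (ms), must be positive.
#' @param sigma Sigmoidicity exponent (dimensionless, > 0); 1 reduces the
#'   curve to a single exponential.
#' @param t0_offset Origin shift (ms) applied before evaluating the rise;
#'   defaults to 0.1 ms, the conventional correction for filter delay and
#'   cell charging in real recordings.
#' @export
activation_fit <- function(amplitude, tau_act, sigma = 1, t0_offset = 0.1) {
  if (!is.numeric(tau_act) || tau_act <= 0) stop("tau_act must be positive")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (t0_offset < 0) stop("t0_offset must be >= 0")
  structure(list(amplitude = amplitude, tau_act = tau_act, sigma = sigma,
                 t0_offset = t0_offset),
            class = "activation_fit")
}

#' Power-exponential activation time course
#'
#' `I(t) = A * (1 - exp(-t/tau_act))^sigma`, with `t` measured from the
#' shifted origin `t0_offset`. Times before the shifted origin evaluate to 0.
#'
#' @param t Time(s) in ms, measured from the start of the voltage step.
#' @param f An [activation_fit()] object.
#' @export
activation_timecourse <- function(t, f) {
  stopifnot(inherits(f, "activation_fit"))
  tt <- pmax(t - f$t0_offset, 0)
  f$amplitude * (1 - exp(-tt / f$tau_act))^f$sigma
}

#' Bi-exponential relaxation parameters
#'
#' Components are stored fast-first: `tau1 < tau2`. A mono-exponential is
#' encoded as `a2 = 0`.
#'
#' @param y0 Offset (pA) the relaxation decays to.
#' @param a1,a2 Component amplitudes (pA).
#' @param tau1,tau2 Component time constants (ms), both positive.
#' @param t0 Start time of the decay (ms).
#' @export
biexp_fit <- function(y0 = 0, a1, tau1, a2 = 0, tau2 = Inf, t0 = 0) {
  if (tau1 <= 0 || (a2 != 0 && tau2 <= 0)) stop("time constants must be positive")
  if (a2 == 0 && !is.finite(tau2)) tau2 <- Inf
  if (a2 != 0 && tau1 > tau2) {  # keep fast component first
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    tmp <- a1; a1 <- a2; a2 <- tmp
  }
  structure(list(y0 = y0, a1 = a1, tau1 = tau1, a2 = a2, tau2 = tau2, t0 = t0),
            class = "biexp_fit")
}

#' Bi-exponential relaxation time course
#'
#' `y0 + A1*exp(-(t - t0)/tau1) + A2*exp(-(t - t0)/tau2)`.
#'
#' @param t Time(s) in ms; must be `>= t0`.
#' @param f A [biexp_fit()] object.
#' @export
biexp_relaxation <- function(t, f) {
  stopifnot(inherits(f, "biexp_fit"))
  if (any(t < f$t0)) stop("t must be >= t0")
  td <- t - f$t0
  out <- f$y0 + f$a1 * exp(-td / f$tau1)
  if (f$a2 != 0) out <- out + f$a2 * exp(-td / f$tau2)
  out
}

#' Drug-block model for one channel population
#'
#' Equilibrium pore block (RY785-style) is parameterised by a KD/IC50 and a
#' Hill exponent. The saturating voltage-sensor-modulator mechanism
#' (GxTX-style, applied at a single saturating dose) is parameterised by the
#' fraction of conductance remaining at that dose.
#'
#' @param kd_or_ic50 Dissociation constant or IC50 (nM), > 0.
#' @param n Hill exponent (default 1, i.e. 1:1 binding).
#' @param mechanism `"equilibrium_pore_block"` or `"saturating_vsd_modulator"`.
#' @param remaining_fraction For the saturating modulator, fraction of
#'   conductance remaining at the standard dose (0..1).
#' @export
block_model <- function(kd_or_ic50, n = 1,
                        mechanism = c("equilibrium_pore_block",
                                      "saturating_vsd_modulator"),
                        remaining_fraction = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(kd_or_ic50) || kd_or_ic50 <= 0) stop("kd_or_ic50 must be > 0")
  if (!is.numeric(n) || n <= 0) stop("n must be > 0")
  if (mechanism == "saturating_vsd_modulator") {
    if (is.null(remaining_fraction) || remaining_fraction < 0 ||
        remaining_fraction > 1) {
      stop("remaining_fraction in [0, 1] required for saturating_vsd_modulator")
    }
  }
  structure(list(kd_or_ic50 = kd_or_ic50, n = n, mechanism = mechanism,
                 remaining_fraction = remaining_fraction),
            class = "block_model")
}

#' Fraction of conductance not blocked at a given drug concentration
#'
#' For equilibrium pore block: `1 / (1 + (conc/KD)^n)`. For the saturating
#' voltage-sensor modulator, any non-zero dose returns the configured
#' `remaining_fraction` (the model is only used at its standard saturating
#' dose, 100 nM for GxTX).
#'
#' @param conc Drug concentration (nM), >= 0.
#' @param m A [block_model()] object.
#' @return Fraction in (0, 1].
#' @export
unblocked_fraction <- function(conc, m) {
  stopifnot(inherits(m, "block_model"))
  if (any(conc < 0)) stop("concentration must be >= 0")
  if (m$mechanism == "saturating_vsd_modulator") {
    return(ifelse(conc > 0, m$remaining_fraction, 1))
  }
  1 / (1 + (conc / m$kd_or_ic50)^m$n)
}

#' Hill concentration-effect parameters
#'
#' Response is expressed as a fraction of a reference measurement; the top is
#' fixed at 1 and `base` is the fraction remaining at a saturating blocker
#' concentration.
#'
#' @param ic50 Half-maximal inhibitory concentration (nM), > 0.
#' @param n_hill Hill coefficient, > 0.
#' @param base Fraction remaining at saturating concentration, in [0, 1).
#' @export
hill_fit <- function(ic50, n_hill = 1, base = 0) {
  if (!is.numeric(ic50) || ic50 <= 0) stop("ic50 must be > 0")
  if (!is.numeric(n_hill) || n_hill <= 0) stop("n_hill must be > 0")
  if (base < 0 || base >= 1) stop("base must be in [0, 1)")
  structure(list(ic50 = ic50, n_hill = n_hill, base = base),
            class = "hill_fit")
}

#' Hill concentration-effect curve
#'
#' `base + (1 - base) / (1 + (conc/IC50)^nH)`, top fixed at 1.
#'
#' @param conc Concentration(s), nM, >= 0.
#' @param h A [hill_fit()] object.
#' @export
hill_response <- function(conc, h) {
  stopifnot(inherits(h, "hill_fit"))
  if (any(conc < 0)) stop("concentration must be >= 0")
  h$base + (1 - h$base) / (1 + (conc / h$ic50)^h$n_hill)
}

#' Nernst equilibrium potential
#'
#' `(R*T / (valence*F)) * ln(conc_out / conc_in)`, in mV.
#'
#' @param conc_in,conc_out Intracellular / extracellular concentrations (mM),
#'   both > 0.
#' @param valence Ion valence (integer, non-zero).
#' @param const A [phys_constants()] object.
#' @export
nernst_potential <- function(conc_in, conc_out, valence = 1,
                             const = phys_constants()) {
  if (any(conc_in <= 0) || any(conc_out <= 0)) {
    stop("concentrations must be > 0")
  }
  if (valence == 0) stop("valence must be non-zero")
  (const$rt_over_f_mV / valence) * log(conc_out / conc_in)
}
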