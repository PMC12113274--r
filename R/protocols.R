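# Voltage protocols: ordered command-voltage epochs with a leading holding
# segment. Presets encode the step/tail structures used for CHO cell and
# sensory-neuron recordings; all voltages are liquid-junction-corrected.

#' Build a voltage protocol
#'
#' Either pick a named preset or supply an explicit epoch table. Every
#' protocol starts with an implicit holding segment (`pre_hold_ms`) at the
#' holding potential so traces carry a baseline. Voltages are reported
#' liquid-junction-corrected; the `ljp` field records the offset that is
#' already included.
#'
#' Presets:
#' \describe{
#'   \item{cho_activation_family}{Hold -89 mV; 200 ms steps over a 10 mV grid
#'     from -79 to +71 mV; 300 ms tail at -9 mV. LJP -9 mV.}
#'   \item{cho_dose_response}{Hold -89 mV; 200 ms step to +71 mV; 300 ms tail
#'     at -9 mV; sweeps every 5 s. LJP -9 mV.}
#'   \item{cho_inactivation_10s}{Hold -89 mV; single 10 s step to -9 mV.}
#'   \item{cho_ssi_family}{Hold -89 mV; 10 s conditioning holds over a 10 mV
#'     grid from -109 to -19 mV, each followed by a 500 ms test step to
#'     -9 mV (long enough for activation to equilibrate at the test
#'     voltage).}
#'   \item{scg_tail}{Hold -74 mV; 200 ms step to +5 mV; 300 ms tail at
#'     -45 mV. LJP -15 mV.}
#'   \item{drg_tail}{Hold -74 mV; 200 ms step to +6 mV; 300 ms tail at
#'     -44 mV. LJP -4 mV.}
#' }
#'
#' @param preset Preset name, or `NULL` when `epochs` is given.
#' @param epochs Optional data frame with columns `voltage` (mV), `duration`
#'   (ms) and `role` (one of `"step"`, `"tail"`, `"hold"`, `"test"`).
#' @param step_voltages Optional vector of voltages turning the protocol into
#'   a family: each voltage replaces the varied epoch (`vary_role`) in one
#'   sweep of the family.
#' @param holding Holding potential (mV); required with explicit `epochs`.
#' @param sample_interval Sampling interval (ms).
#' @param inter_sweep_interval Seconds between sweeps.
#' @param pre_hold_ms Length of the leading holding segment (ms).
#' @param ljp Liquid junction potential already applied to voltages (mV).
#' @param vary_role Which epoch role `step_voltages` replaces.
#' @param name Protocol name.
#' @return A `voltage_protocol` list.
#' @export
build_protocol <- function(preset = NULL, epochs = NULL, step_voltages = NULL,
                           holding = NULL, sample_interval = NULL,
                           inter_sweep_interval = NULL, pre_hold_ms = 20,
                           ljp = 0, vary_role = "step", name = NULL) {
  presets <- list(
    cho_activation_family = list(
      holding = -89,
      epochs = data.frame(voltage = c(-9, -9), duration = c(200, 300),
                          role = c("step", "tail")),
      step_voltages = seq(-79, 71, by = 10),
      sample_interval = 0.05, inter_sweep_interval = 6, ljp = -9,
      vary_role = "step"),
    cho_dose_response = list(
      holding = -89,
      epochs = data.frame(voltage = c(71, -9), duration = c(200, 300),
                          role = c("step", "tail")),
      step_voltages = NULL,
      sample_interval = 0.1, inter_sweep_interval = 5, ljp = -9,
      vary_role = "step"),
    cho_inactivation_10s = list(
      holding = -89,
      epochs = data.frame(voltage = -9, duration = 10000, role = "step"),
      step_voltages = NULL,
      sample_interval = 1, inter_sweep_interval = 30, ljp = -9,
      vary_role = "step"),
    cho_ssi_family = list(
      holding = -89,
      epochs = data.frame(voltage = c(-89, -9), duration = c(10000, 500),
                          role = c("hold", "test")),
      step_voltages = seq(-109, -19, by = 10),
      sample_interval = 1, inter_sweep_interval = 30, ljp = -9,
      vary_role = "hold"),
    scg_tail = list(
      holding = -74,
      epochs = data.frame(voltage = c(5, -45), duration = c(200, 300),
                          role = c("step", "tail")),
      step_voltages = NULL,
      sample_interval = 0.05, inter_sweep_interval = 6, ljp = -15,
      vary_role = "step"),
    drg_tail = list(
      holding = -74,
      epochs = data.frame(voltage = c(6, -44), duration = c(200, 300),
                          role = c("step", "tail")),
      step_voltages = NULL,
      sample_interval = 0.05, inter_sweep_interval = 6, ljp = -4,
      vary_role = "step"))

  if (!is.null(preset)) {
    if (!preset %in% names(presets)) {
      stop("unknown protocol preset: ", preset,
           " (available: ", paste(names(presets), collapse = ", "), ")")
    }
    p <- presets[[preset]]
    if (is.null(name)) name <- preset
    if (is.null(holding)) holding <- p$holding
    if (is.null(epochs)) epochs <- p$epochs
    if (is.null(step_voltages)) step_voltages <- p$step_voltages
    if (is.null(sample_interval)) sample_interval <- p$sample_interval
    if (is.null(inter_sweep_interval)) {
      inter_sweep_interval <- p$inter_sweep_interval
    }
    if (missing(ljp)) ljp <- p$ljp
    if (missing(vary_role)) vary_role <- p$vary_role
  } else {
    if (is.null(epochs) || is.null(holding)) {
      stop("either a preset or explicit epochs + holding must be given")
    }
    if (is.null(name)) name <- "custom"
    if (is.null(sample_interval)) sample_interval <- 0.05
    if (is.null(inter_sweep_interval)) inter_sweep_interval <- 6
  }
  stopifnot(is.data.frame(epochs),
            all(c("voltage", "duration", "role") %in% names(epochs)))
  if (any(epochs$duration <= 0)) stop("epoch durations must be positive")
  if (sample_interval <= 0) stop("sample_interval must be positive")
  if (pre_hold_ms <= 0) stop("pre_hold_ms must be positive")
  if (!is.null(step_voltages) && !vary_role %in% epochs$role) {
    stop("vary_role '", vary_role, "' not present in epochs")
  }
  structure(
    list(name = name, holding = holding, epochs = epochs,
         step_voltages = step_voltages, sample_interval = sample_interval,
         inter_sweep_interval = inter_sweep_interval,
         pre_hold_ms = pre_hold_ms, ljp = ljp, vary_role = vary_role),
    class = "voltage_protocol")
}

# full epoch table for one sweep of a protocol (leading hold included),
# with absolute start/end times
.sweep_epochs <- function(protocol, step_voltage = NULL) {
  ep <- protocol$epochs
  if (!is.null(step_voltage)) {
    ep$voltage[ep$role == protocol$vary_role] <- step_voltage
  }
  ep <- rbind(data.frame(voltage = protocol$holding,
                         duration = protocol$pre_hold_ms, role = "pre_hold"),
              ep)
  ep$start <- cumsum(c(0, ep$duration[-nrow(ep)]))
  ep$end <- ep$start + ep$duration
  ep
}
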