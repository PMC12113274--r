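# Preset model cells. Each preset is a JSON config under
# inst/extdata/presets/ transcribing published gating and drug-sensitivity
# parameters (every transcribed value carries a provenance string); the
# population weights are calibrated so the full simulate -> measure ->
# subtract pipeline reproduces the published headline fractions.

#' List available cell presets
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  files <- list.files(system.file("extdata", "presets",
                                  package = "kvsdissect"),
                      pattern = "\\.json$")
  sort(sub("\\.json$", "", files))
}

#' Read a preset's raw configuration
#'
#' @param preset Preset name (see [list_presets()]).
#' @return The parsed configuration list, including provenance strings.
#' @export
preset_config <- function(preset) {
  path <- system.file("extdata", "presets", paste0(preset, ".json"),
                      package = "kvsdissect")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown preset: ", preset,
         " (available: ", paste(list_presets(), collapse = ", "), ")")
  }
  jsonlite::read_json(path)
}

# list of row-lists -> data frame
.rows_to_df <- function(rows) {
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

# build one population_spec from its config entry
.population_from_config <- function(p) {
  act <- boltzmann_params(amplitude = 1, v_half = p$activation$v_half_mV,
                          z = p$activation$z, direction = "activation")
  inact <- NULL
  floor <- 1
  if (!is.null(p$inactivation) && length(p$inactivation) > 0) {
    inact <- boltzmann_params(amplitude = 1,
                              v_half = p$inactivation$v_half_mV,
                              z = p$inactivation$z,
                              direction = "inactivation")
    floor <- p$inactivation$floor
  }
  ry <- NULL
  if (!is.null(p$ry785) && length(p$ry785) > 0) {
    ry <- block_model(kd_or_ic50 = p$ry785$ic50_nM, n = p$ry785$n)
  }
  ak <- .rows_to_df(p$act_kinetics)
  dk <- .rows_to_df(p$deact_kinetics)
  population_spec(
    name = p$name, gmax = p$gmax_nS, activation = act,
    act_kinetics = data.frame(voltage = ak$voltage_mV, tau = ak$tau_ms,
                              sigma = ak$sigma),
    deact_kinetics = data.frame(voltage = dk$voltage_mV,
                                tau_fast = dk$tau_fast_ms,
                                tau_slow = dk$tau_slow_ms,
                                frac_fast = dk$frac_fast),
    inactivation = inact, inact_floor = floor,
    tau_inact = if (is.null(p$tau_inact_ms)) 2000 else p$tau_inact_ms,
    ry785 = ry, gxtx_remaining = p$gxtx_remaining,
    reversal = p$reversal_mV)
}

#' Build a preset model cell
#'
#' Presets: `cho_kv2_only` (Kv2.1 homomer expression system),
#' `cho_kv8_1_mix` (Kv2.1 homomers plus Kv2.1/Kv8.1 heteromers),
#' `scg` (superior cervical ganglion neuron: homomer-dominant plus a
#' drug-insensitive background), `mrgprd_drg` / `calca_drg` (mouse
#' nonpeptidergic / peptidergic nociceptors: Kv2-only, Kv2/KvS and background
#' populations) and `human_drg` (human DRG neuron, KvS-dominant).
#'
#' Noise and rundown are part of each preset's configuration but default to
#' off so that deterministic analyses are the baseline; enable them for
#' realistic traces.
#'
#' @param preset Preset name.
#' @param noise Enable the configured additive Gaussian noise?
#' @param rundown Enable the configured multiplicative rundown?
#' @param seed RNG seed (required when `noise = TRUE`).
#' @param noise_sd Override the configured noise SD (pA).
#' @return A [cell_model()] with attribute `"preset"`.
#' @export
make_preset_cell <- function(preset, noise = FALSE, rundown = FALSE,
                             seed = NULL, noise_sd = NULL) {
  cfg <- preset_config(preset)
  pops <- lapply(cfg$populations, .population_from_config)
  sd_pA <- if (noise) {
    if (is.null(noise_sd)) cfg$noise_sd_pA else noise_sd
  } else 0
  rd <- if (rundown) {
    list(rate = cfg$rundown$rate, floor = cfg$rundown$floor)
  } else {
    list(rate = 0, floor = 1)
  }
  cell <- cell_model(
    populations = pops, leak_conductance = cfg$leak_conductance_nS,
    leak_reversal = cfg$leak_reversal_mV, noise_sd = sd_pA, rundown = rd,
    seed = seed, temperature_K = cfg$temperature_K, id = cfg$name)
  attr(cell, "preset") <- preset
  attr(cell, "config") <- cfg
  cell
}

#' Default protocol and tail window of a preset
#'
#' @param preset Preset name or a cell built by [make_preset_cell()].
#' @return List with `protocol` (a [build_protocol()] object) and `window`
#'   (a [tail_window()]).
#' @export
preset_defaults <- function(preset) {
  cfg <- if (inherits(preset, "cell_model")) {
    attr(preset, "config")
  } else {
    preset_config(preset)
  }
  w <- cfg$tail_window
  list(protocol = build_protocol(cfg$protocol),
       window = tail_window(mode = w$mode, start = w$start,
                            end = if (is.null(w$end)) w$start + 1 else w$end))
}

#' Extract a single-population variant of a preset cell
#'
#' Convenience for characterising one population in isolation (e.g. the
#' heteromer entry of the CHO mix): returns a cell containing only the named
#' population, other settings unchanged.
#'
#' @param cell A cell from [make_preset_cell()].
#' @param name Population name.
#' @export
single_population_cell <- function(cell, name) {
  stopifnot(inherits(cell, "cell_model"))
  if (!name %in% names(cell$populations)) {
    stop("population '", name, "' not in cell (has: ",
         paste(names(cell$populations), collapse = ", "), ")")
  }
  cell$populations <- cell$populations[name]
  cell
}
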