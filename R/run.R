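# High-level entry points tying the generator and the pipeline together:
# simulate a preset to disk, analyze recordings into a decomposition report,
# and run a concentration-effect experiment. These back the command-line
# script shipped in inst/cli/kvsdissect.R.

.log_msg <- function(level, ..., verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", level, paste0(...)))
}

# light-weight polynomial hash of the serialized config for run logs
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 268435399
  sprintf("%08x", h)
}

.validate_run_config <- function(config) {
  problems <- character()
  if (is.null(config$preset)) problems <- c(problems, "preset: required")
  else if (!config$preset %in% list_presets()) {
    problems <- c(problems, paste0("preset: unknown ('", config$preset, "')"))
  }
  noise <- isTRUE(config$noise)
  rundown <- isTRUE(config$rundown)
  if ((noise || rundown) && is.null(config$seed)) {
    problems <- c(problems, "seed: required when noise or rundown is enabled")
  }
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed))) {
    problems <- c(problems, "seed: must be an integer")
  }
  if (length(problems)) {
    stop("invalid run config:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Simulate a preset recording to disk
#'
#' Writes one recording directory per condition (`condition_<name>/` with
#' `sweeps.csv` + `recording.json`) plus a machine-readable `run_log.json`
#' (seed, package version, config hash) sufficient to reproduce the outputs
#' exactly. Re-running with the same config overwrites with identical
#' content.
#'
#' @param config List (or path to a JSON file) with fields: `preset`
#'   (required), `out_dir` (required), `conditions` (default baseline /
#'   ry785 / ry785_gxtx), `noise`, `rundown` (logicals, default off), `seed`
#'   (required when noise or rundown is on).
#' @param verbose Emit progress messages?
#' @return Output directory, invisibly.
#' @export
run_simulate <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  .validate_run_config(config)
  if (is.null(config$out_dir)) stop("invalid run config:\n  out_dir: required")
  conditions <- unlist(config$conditions)
  if (is.null(conditions)) conditions <- c("baseline", "ry785", "ry785_gxtx")
  cell <- make_preset_cell(config$preset, noise = isTRUE(config$noise),
                           rundown = isTRUE(config$rundown),
                           seed = config$seed)
  defs <- preset_defaults(cell)
  cfg <- attr(cell, "config")
  .log_msg("INFO", "preset ", config$preset, ": ", cfg$description,
           verbose = verbose)
  for (pop in cfg$populations) {
    .log_msg("INFO", "  population ", pop$name, ": ", pop$provenance,
             verbose = verbose)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in conditions) {
    rec <- simulate_recording(cell, defs$protocol, conditions = cond,
                              noise = isTRUE(config$noise),
                              preset = config$preset)
    dest <- file.path(config$out_dir, paste0("condition_", cond))
    write_recording(rec, dest)
    .log_msg("INFO", "wrote ", dest, verbose = verbose)
  }
  log <- list(tool = "kvsdissect", command = "simulate",
              version = as.character(utils::packageVersion("kvsdissect")),
              seed = config$seed, preset = config$preset,
              conditions = conditions,
              noise = isTRUE(config$noise), rundown = isTRUE(config$rundown),
              config_hash = .config_hash(config[order(names(config))]))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(config$out_dir)
}

#' Analyze simulated (or imported) recordings
#'
#' Loads the per-condition recordings from a directory produced by
#' [run_simulate()], runs the subtraction decomposition, fits deactivation
#' of the Kv2-like component (standard arm), and writes `report.json` and a
#' tidy `summary.csv`. A vehicle-only arm yields the combined Kv2+KvS-like
#' report instead.
#'
#' @param dir Directory containing `condition_*` subdirectories.
#' @param tail_mode,tail_start,tail_end Tail window override (defaults come
#'   from the preset recorded in the metadata, falling back to the 1--5 ms
#'   mean).
#' @param out_dir Where to write the report (default: `dir`).
#' @param verbose Emit progress messages?
#' @return The report list, invisibly.
#' @export
run_analyze <- function(dir, tail_mode = NULL, tail_start = NULL,
                        tail_end = NULL, out_dir = dir, verbose = TRUE) {
  cond_dirs <- list.files(dir, pattern = "^condition_", full.names = TRUE)
  if (length(cond_dirs) == 0L) {
    stop("no condition_* recordings found under ", dir)
  }
  recs <- lapply(cond_dirs, read_recording)
  rec <- recs[[1]]
  rec$sweeps <- do.call(c, lapply(recs, `[[`, "sweeps"))
  preset <- rec$metadata$preset
  w <- if (!is.null(preset) && !is.na(preset) && preset %in% list_presets()) {
    preset_defaults(preset)$window
  } else {
    tail_window("mean_window", 1, 5)
  }
  if (!is.null(tail_mode)) {
    w <- tail_window(tail_mode,
                     start = if (is.null(tail_start)) w$start else tail_start,
                     end = if (is.null(tail_end)) w$end else tail_end)
  }
  dec <- decompose(rec, w)
  report <- list(
    tool = "kvsdissect", command = "analyze",
    version = as.character(utils::packageVersion("kvsdissect")),
    source = dir, arm = dec$arm,
    tail_window = list(mode = w$mode, start_ms = w$start,
                       end_ms = if (w$mode == "mean_window") w$end else NULL),
    tails = dec$tails)
  summary_row <- list(cell_id = rec$metadata$cell_id, condition = NA,
                      tail_pA = NA, pct_inhib_ry785 = NA,
                      pct_inhib_gxtx = NA, fractional_kvs = NA,
                      v_half = NA, z = NA, tau_fast_ms = NA)
  if (dec$arm == "standard") {
    report$percent_inhibition_ry785 <- dec$percent_inhibition_ry785
    report$percent_inhibition_gxtx_additional <-
      dec$percent_inhibition_gxtx_additional
    report$percent_inhibition_gxtx_vs_ry785 <-
      dec$percent_inhibition_gxtx_vs_ry785
    report$fractional_kvs <- dec$fractional_kvs
    report$flags <- dec$flags
    tau <- tryCatch({
      f <- fit_deactivation(dec$kv2_like[[1]])
      list(tau_fast_ms = f$fit$tau1, converged = f$diagnostics$converged,
           window_ms = f$diagnostics$window)
    }, error = function(e) list(error = conditionMessage(e)))
    report$kv2_like_deactivation <- tau
    gv <- tryCatch({
      pts <- extract_gv(dec$kv2_like, w)
      bf <- fit_boltzmann(pts)
      list(v_half_mV = bf$fit$v_half, z = bf$fit$z,
           converged = bf$diagnostics$converged)
    }, error = function(e) NULL)
    report$kv2_like_gv <- gv
    summary_row$pct_inhib_ry785 <- dec$percent_inhibition_ry785
    summary_row$pct_inhib_gxtx <- dec$percent_inhibition_gxtx_additional
    summary_row$fractional_kvs <- dec$fractional_kvs
    if (!is.null(gv)) {
      summary_row$v_half <- gv$v_half_mV
      summary_row$z <- gv$z
    }
    if (!is.null(tau$tau_fast_ms)) summary_row$tau_fast_ms <- tau$tau_fast_ms
    tail_cols <- c(baseline = "tail_baseline", ry785 = "tail_ry785",
                   ry785_gxtx = "tail_ry785_gxtx")
  } else {
    report$percent_inhibition_ry785_gxtx <-
      dec$percent_inhibition_ry785_gxtx
    tail_cols <- c(vehicle = "tail_vehicle", ry785_gxtx = "tail_residual")
  }
  summary <- do.call(rbind, lapply(names(tail_cols), function(cond) {
    row <- summary_row
    row$condition <- cond
    row$tail_pA <- sum(dec$tails[[tail_cols[[cond]]]])
    as.data.frame(row)
  }))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  .log_msg("INFO", "wrote ", file.path(out_dir, "report.json"),
           verbose = verbose)
  invisible(report)
}

#' Run a concentration-effect experiment and Hill fit
#'
#' Simulates the configured preset across a concentration ladder, extracts
#' per-concentration plateau tail amplitudes normalized at the reference
#' concentration, and fits the Hill model both with the coefficient fixed
#' (default 1) and free.
#'
#' @param config List (or JSON path) with fields `preset` (required),
#'   `concs_uM` (default the standard ladder 0.35, 1.1, 3.5, 11, 35),
#'   `sweeps_per_conc` (default 7), `noise`, `rundown`, `seed`, `fix_nh`
#'   (default 1), optional `out` (JSON report path).
#' @param verbose Emit progress messages?
#' @return List with the series and both Hill fits.
#' @export
run_dose_response <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  .validate_run_config(config)
  concs_uM <- unlist(config$concs_uM)
  if (is.null(concs_uM)) concs_uM <- c(0.35, 1.1, 3.5, 11, 35)
  if (length(concs_uM) < 3L) {
    stop("invalid run config:\n  concs_uM: at least 3 concentrations required")
  }
  concs <- sort(concs_uM) * 1000  # internal unit is nM
  spc <- if (is.null(config$sweeps_per_conc)) 7 else config$sweeps_per_conc
  cell <- make_preset_cell(config$preset, noise = isTRUE(config$noise),
                           rundown = isTRUE(config$rundown),
                           seed = config$seed)
  proto <- build_protocol("cho_dose_response")
  rec <- simulate_dose_response(cell, proto, concs, sweeps_per_conc = spc,
                                noise = isTRUE(config$noise))
  series <- dose_response_series(rec, reference_conc = concs[1])
  fix_nh <- if (is.null(config$fix_nh)) 1 else config$fix_nh
  fit_fixed <- fit_hill(series$conc_nM, series$response,
                        fix_n_hill = fix_nh, reference_conc = concs[1])
  fit_free <- fit_hill(series$conc_nM, series$response, fix_n_hill = NULL,
                       reference_conc = concs[1])
  .log_msg("INFO", sprintf(
    "Hill fit (nH = %g): IC50 = %.3g uM, base = %.3g",
    fix_nh, fit_fixed$fit$ic50 / 1000, fit_fixed$fit$base),
    verbose = verbose)
  .log_msg("INFO", sprintf(
    "Hill fit (nH free): IC50 = %.3g uM, nH = %.3g",
    fit_free$fit$ic50 / 1000, fit_free$fit$n_hill), verbose = verbose)
  out <- list(series = series,
              hill_fixed = list(ic50_nM = fit_fixed$fit$ic50,
                                n_hill = fit_fixed$fit$n_hill,
                                base = fit_fixed$fit$base,
                                converged = fit_fixed$diagnostics$converged),
              hill_free = list(ic50_nM = fit_free$fit$ic50,
                               n_hill = fit_free$fit$n_hill,
                               base = fit_free$fit$base,
                               converged = fit_free$diagnostics$converged),
              seed = config$seed, preset = config$preset,
              config_hash = .config_hash(config[order(names(config))]))
  if (!is.null(config$out)) {
    jsonlite::write_json(out, config$out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  }
  out
}
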