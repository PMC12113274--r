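# Sweep interchange format: a long CSV (sweep_id, time_ms, voltage_mV,
# current_pA) plus a JSON sidecar holding recording metadata and per-sweep
# attributes. Numeric values are written with 17 significant digits so the
# round trip is lossless for doubles.

.SWEEP_COLUMNS <- c("sweep_id", "time_ms", "voltage_mV", "current_pA")

#' Write a recording to a directory
#'
#' Produces `sweeps.csv` (long format, UTF-8, '.' decimal) and
#' `recording.json` (metadata plus per-sweep condition, concentrations, step
#' voltage, epoch table and flags).
#'
#' @param rec A `kvs_recording`.
#' @param path Directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "kvs_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(rec$sweeps, function(s) {
    data.frame(sweep_id = s$sweep_id,
               time_ms = sprintf("%.17g", s$time),
               voltage_mV = sprintf("%.17g", s$voltage),
               current_pA = sprintf("%.17g", s$current))
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(path, "sweeps.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  sidecar <- list(
    format = "kvsdissect-recording",
    version = 1L,
    metadata = rec$metadata,
    sweeps = lapply(rec$sweeps, function(s) {
      list(sweep_id = s$sweep_id, condition = s$condition,
           conc_ry785_nM = s$conc_ry785, conc_gxtx_nM = s$conc_gxtx,
           step_voltage_mV = s$step_voltage, sweep_index = s$sweep_index,
           conc_stage = s$conc_stage,
           p4_subtracted = s$p4_subtracted,
           epochs = lapply(seq_len(nrow(s$epochs)), function(k) {
             as.list(s$epochs[k, c("voltage", "duration", "role")])
           }))
    }))
  jsonlite::write_json(sidecar, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording back from a directory
#'
#' Validates the sidecar and the CSV; malformed files raise an error naming
#' the offending field or column.
#'
#' @param path Directory written by [write_recording()].
#' @return A `kvs_recording`.
#' @export
read_recording <- function(path) {
  csv_path <- file.path(path, "sweeps.csv")
  json_path <- file.path(path, "recording.json")
  if (!file.exists(csv_path)) stop("missing sweeps.csv in ", path)
  if (!file.exists(json_path)) stop("missing recording.json in ", path)
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         colClasses = c(sweep_id = "character"))
  missing <- setdiff(.SWEEP_COLUMNS, names(tab))
  if (length(missing)) {
    stop("sweeps.csv is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("time_ms", "voltage_mV", "current_pA")) {
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop("non-numeric value in column ", col, " at data row ", bad)
    }
  }
  sidecar <- jsonlite::read_json(json_path)
  if (is.null(sidecar$metadata)) stop("recording.json lacks 'metadata'")
  if (is.null(sidecar$sweeps)) stop("recording.json lacks 'sweeps'")
  meta <- sidecar$metadata
  if (!is.null(meta$seed)) meta$seed <- as.integer(meta$seed)
  meta$conditions <- unlist(meta$conditions)
  sweeps <- lapply(sidecar$sweeps, function(info) {
    req <- c("sweep_id", "condition", "conc_ry785_nM", "conc_gxtx_nM",
             "step_voltage_mV", "sweep_index", "epochs")
    miss <- req[vapply(req, function(f) is.null(info[[f]]), TRUE)]
    if (length(miss)) {
      stop("recording.json sweep entry missing field(s): ",
           paste(miss, collapse = ", "))
    }
    rows <- tab[tab$sweep_id == info$sweep_id, ]
    if (nrow(rows) == 0L) {
      stop("sweeps.csv has no rows for sweep_id ", info$sweep_id)
    }
    ep <- do.call(rbind, lapply(info$epochs, function(e) {
      data.frame(voltage = e$voltage, duration = e$duration, role = e$role)
    }))
    ep$start <- cumsum(c(0, ep$duration[-nrow(ep)]))
    ep$end <- ep$start + ep$duration
    structure(
      list(sweep_id = info$sweep_id, condition = info$condition,
           conc_ry785 = info$conc_ry785_nM, conc_gxtx = info$conc_gxtx_nM,
           step_voltage = info$step_voltage_mV,
           sweep_index = as.integer(info$sweep_index),
           time = rows$time_ms, voltage = rows$voltage_mV,
           current = rows$current_pA,
           p4_subtracted = isTRUE(info$p4_subtracted),
           conc_stage = info$conc_stage,
           epochs = ep),
      class = "kvs_sweep")
  })
  structure(list(metadata = meta, sweeps = sweeps), class = "kvs_recording")
}
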