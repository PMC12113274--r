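# The inference pipeline: condition-matched tail measurement, subtraction
# decomposition into Kv2-like / KvS-like / residual components, percent
# inhibition, fractional KvS-like conductance, G-V extraction, concentration-
# effect series and inactivation metrics.

#' Tail-current measurement window
#'
#' @param mode `"mean_window"` (average over `[start, end)` ms after tail
#'   onset, the CHO convention: 1--5 ms) or `"point"` (linear interpolation
#'   at `start` ms, the neuron convention: 10 ms).
#' @param start Window start / point time, ms after the tail step.
#' @param end Window end (mean_window only), ms.
#' @export
tail_window <- function(mode = c("mean_window", "point"), start = 1,
                        end = 5) {
  mode <- match.arg(mode)
  if (mode == "mean_window" && !(start >= 0 && start < end)) {
    stop("mean_window requires 0 <= start < end")
  }
  if (mode == "point" && start < 0) stop("point time must be >= 0")
  structure(list(mode = mode, start = start, end = end),
            class = "tail_window")
}

#' Measure a tail-current amplitude
#'
#' @param sweep A `kvs_sweep`.
#' @param w A [tail_window()].
#' @param role Epoch role to measure in (`"tail"`, or `"test"` for SSI test
#'   steps).
#' @return Amplitude in pA.
#' @export
measure_tail <- function(sweep, w = tail_window(), role = "tail") {
  stopifnot(inherits(sweep, "kvs_sweep"), inherits(w, "tail_window"))
  tr <- .epoch_samples(sweep, role)
  if (w$mode == "mean_window") {
    if (w$end > tr$duration) stop("tail window extends beyond the epoch")
    sel <- tr$t >= w$start & tr$t < w$end
    if (!any(sel)) stop("tail window contains no samples")
    mean(tr$i[sel])
  } else {
    if (w$start > max(tr$t)) stop("tail point lies beyond the epoch")
    stats::approx(tr$t, tr$i, xout = w$start)$y
  }
}

# index recording sweeps by condition -> list keyed by step voltage
.sweeps_by_condition <- function(rec, condition) {
  sel <- Filter(function(s) s$condition == condition, rec$sweeps)
  if (length(sel) == 0L) return(NULL)
  names(sel) <- vapply(sel, function(s) sprintf("%.3f", s$step_voltage), "")
  sel
}

#' Subtract one drug condition from another, sweep by sweep
#'
#' Pairs sweeps of the two conditions by step voltage and returns their
#' sample-wise differences (minuend minus subtrahend). This is the
#' subtraction that defines the Kv2-like (baseline minus RY785) and KvS-like
#' (RY785 minus RY785+GxTX) currents.
#'
#' @param rec A `kvs_recording`.
#' @param minuend,subtrahend Condition names present in the recording.
#' @return List of difference `kvs_sweep`s (condition labelled
#'   `"minuend-subtrahend"`).
#' @export
subtract_conditions <- function(rec, minuend, subtrahend) {
  stopifnot(inherits(rec, "kvs_recording"))
  a <- .sweeps_by_condition(rec, minuend)
  b <- .sweeps_by_condition(rec, subtrahend)
  if (is.null(a)) stop("condition '", minuend, "' not present in recording")
  if (is.null(b)) stop("condition '", subtrahend, "' not present in recording")
  if (!setequal(names(a), names(b))) {
    stop("step voltages do not match between conditions '", minuend,
         "' and '", subtrahend, "'")
  }
  lapply(names(a), function(k) {
    sa <- a[[k]]; sb <- b[[k]]
    if (length(sa$current) != length(sb$current) ||
        !isTRUE(all.equal(sa$time, sb$time))) {
      stop("protocols differ between conditions at step voltage ", k)
    }
    out <- sa
    out$current <- sa$current - sb$current
    out$condition <- paste0(minuend, "-", subtrahend)
    out$sweep_id <- paste0(sa$sweep_id, "_minus_", sb$condition)
    out
  })
}

#' Decompose a recording into Kv2-like, KvS-like and residual components
#'
#' With the standard arm (baseline, RY785, RY785+GxTX): Kv2-like is baseline
#' minus RY785, KvS-like is RY785 minus RY785+GxTX, residual is what remains
#' in both drugs. With a vehicle arm (vehicle, RY785+GxTX) the combined
#' "Kv2+KvS-like" component (vehicle minus RY785+GxTX) is reported instead
#' and is not split further.
#'
#' Reported scalars (tails summed over step voltages):
#' `percent_inhibition_ry785` = 100 (1 - tail_RY785 / tail_baseline);
#' `percent_inhibition_gxtx_additional` = additional GxTX inhibition
#' referenced to the baseline tail (the paper's referent), with
#' `percent_inhibition_gxtx_vs_ry785` also given referenced to the RY785
#' level; `fractional_kvs` = tail(KvS-like) / (tail(Kv2-like) +
#' tail(KvS-like)), i.e. relative to the total drug-sensitive conductance,
#' the residual excluded by definition. Negative component tails are clamped
#' to zero for `fractional_kvs` (with a warning); raw values are retained in
#' the tail table.
#'
#' @param rec A `kvs_recording`.
#' @param w A [tail_window()].
#' @return A `decomposition_result` list: component sweeps, per-voltage tail
#'   table, and the scalar summaries.
#' @export
decompose <- function(rec, w = tail_window()) {
  stopifnot(inherits(rec, "kvs_recording"))
  conds <- unique(vapply(rec$sweeps, `[[`, "", "condition"))
  vehicle_arm <- !("baseline" %in% conds) && "vehicle" %in% conds
  if (vehicle_arm) {
    if (!"ry785_gxtx" %in% conds) {
      stop("vehicle arm requires conditions 'vehicle' and 'ry785_gxtx'")
    }
    combined <- subtract_conditions(rec, "vehicle", "ry785_gxtx")
    resid <- .sweeps_by_condition(rec, "ry785_gxtx")
    tails <- data.frame(
      step_voltage = vapply(combined, `[[`, 0, "step_voltage"),
      tail_vehicle = vapply(.sweeps_by_condition(rec, "vehicle"),
                            measure_tail, 0, w = w),
      tail_kv2_kvs_like = vapply(combined, measure_tail, 0, w = w),
      tail_residual = vapply(resid, measure_tail, 0, w = w))
    pct <- 100 * (1 - sum(tails$tail_residual) / sum(tails$tail_vehicle))
    return(structure(
      list(arm = "vehicle", kv2_kvs_like = combined, residual = resid,
           tails = tails, percent_inhibition_ry785_gxtx = pct,
           window = w),
      class = "decomposition_result"))
  }
  needed <- c("baseline", "ry785", "ry785_gxtx")
  missing <- setdiff(needed, conds)
  if (length(missing)) {
    stop("recording lacks condition(s): ", paste(missing, collapse = ", "))
  }
  kv2_like <- subtract_conditions(rec, "baseline", "ry785")
  kvs_like <- subtract_conditions(rec, "ry785", "ry785_gxtx")
  resid <- .sweeps_by_condition(rec, "ry785_gxtx")
  base <- .sweeps_by_condition(rec, "baseline")
  ry <- .sweeps_by_condition(rec, "ry785")
  tails <- data.frame(
    step_voltage = vapply(kv2_like, `[[`, 0, "step_voltage"),
    tail_baseline = vapply(base, measure_tail, 0, w = w),
    tail_ry785 = vapply(ry, measure_tail, 0, w = w),
    tail_ry785_gxtx = vapply(resid, measure_tail, 0, w = w),
    tail_kv2_like = vapply(kv2_like, measure_tail, 0, w = w),
    tail_kvs_like = vapply(kvs_like, measure_tail, 0, w = w))
  tails$tail_residual <- tails$tail_ry785_gxtx
  tb <- sum(tails$tail_baseline)
  tr <- sum(tails$tail_ry785)
  tg <- sum(tails$tail_ry785_gxtx)
  kv2 <- sum(tails$tail_kv2_like)
  kvs <- sum(tails$tail_kvs_like)
  flags <- character()
  kv2c <- kv2; kvsc <- kvs
  if (kv2c < 0 || kvsc < 0) {
    warning("negative component tail clamped to 0 for fractional_kvs")
    flags <- c(flags, "negative_component_tail_clamped")
    kv2c <- max(kv2c, 0); kvsc <- max(kvsc, 0)
  }
  frac <- if (kv2c + kvsc <= 0) {
    flags <- c(flags, "fractional_kvs_undefined: no drug-sensitive tail")
    NA_real_
  } else {
    kvsc / (kv2c + kvsc)
  }
  structure(
    list(arm = "standard", kv2_like = kv2_like, kvs_like = kvs_like,
         residual = resid, tails = tails,
         percent_inhibition_ry785 = 100 * (1 - tr / tb),
         percent_inhibition_gxtx_additional = 100 * (tr - tg) / tb,
         percent_inhibition_gxtx_vs_ry785 = 100 * (1 - tg / tr),
         fractional_kvs = frac, flags = flags, window = w),
    class = "decomposition_result")
}

#' Extract a conductance-voltage relation from a sweep family
#'
#' One point per step voltage, from the tail amplitude measured at the
#' common tail voltage (tail amplitude indexes the conductance activated by
#' the preceding step since the driving force is fixed).
#'
#' @param sweeps A `kvs_recording` (one condition only), or a list of
#'   `kvs_sweep`s such as a subtraction family.
#' @param w A [tail_window()].
#' @param normalize Normalize conductances to their maximum?
#' @return Data frame with columns `voltage` and `value`, ready for
#'   [fit_boltzmann()].
#' @export
extract_gv <- function(sweeps, w = tail_window(), normalize = TRUE) {
  if (inherits(sweeps, "kvs_recording")) sweeps <- sweeps$sweeps
  stopifnot(all(vapply(sweeps, inherits, TRUE, "kvs_sweep")))
  v <- vapply(sweeps, `[[`, 0, "step_voltage")
  if (length(unique(v)) < 2L) {
    stop("a G-V relation requires a family of step voltages")
  }
  g <- vapply(sweeps, measure_tail, 0, w = w)
  out <- data.frame(voltage = v, value = g)
  out <- out[order(out$voltage), ]
  if (normalize) out$value <- out$value / max(out$value)
  rownames(out) <- NULL
  out
}

#' Per-concentration normalized tail amplitudes of a dose-response series
#'
#' Computes per-sweep tail amplitudes, takes the plateau at each ladder
#' stage as the mean of its final `plateau_k` sweeps, and normalizes to the
#' plateau at the reference concentration.
#'
#' @param rec A `kvs_recording` from [simulate_dose_response()] (sweeps
#'   tagged with `conc_stage`).
#' @param w A [tail_window()] (the concentration-effect convention is the
#'   2--4 ms mean).
#' @param plateau_k Number of final sweeps averaged per stage.
#' @param reference_conc Reference concentration (nM); defaults to the
#'   lowest stage.
#' @return Data frame with `conc_nM`, `response` (fraction of reference) and
#'   `tail_pA` (raw plateau amplitude).
#' @export
dose_response_series <- function(rec, w = tail_window("mean_window", 2, 4),
                                 plateau_k = 3, reference_conc = NULL) {
  stopifnot(inherits(rec, "kvs_recording"))
  stages <- vapply(rec$sweeps, function(s) {
    if (is.null(s$conc_stage)) s$conc_ry785 else s$conc_stage
  }, 0)
  tails <- vapply(rec$sweeps, measure_tail, 0, w = w)
  idx <- vapply(rec$sweeps, `[[`, 0L, "sweep_index")
  uconc <- unique(stages)
  if (is.null(reference_conc)) reference_conc <- min(uconc)
  if (!any(abs(uconc - reference_conc) < 1e-9)) {
    stop("reference concentration ", reference_conc,
         " nM not present in the series")
  }
  plateau <- vapply(uconc, function(cc) {
    sel <- which(stages == cc)
    sel <- sel[order(idx[sel])]
    mean(tails[utils::tail(sel, plateau_k)])
  }, 0)
  ref <- plateau[which(abs(uconc - reference_conc) < 1e-9)[1]]
  out <- data.frame(conc_nM = uconc, tail_pA = plateau,
                    response = plateau / ref)
  out[order(out$conc_nM), ]
}

#' Inactivation metrics from 10-s protocols
#'
#' For a long-step protocol: percent of current inactivated,
#' `100 (1 - I_end / I_peak)`, with the peak located on a smoothed trace and
#' the end level averaged over the final 2% of the step. For a conditioning
#' family (10-s holds followed by a test step): steady-state availability
#' points, min-max normalized, ready for an inactivation-direction Boltzmann
#' fit.
#'
#' @param rec A `kvs_recording` from the `cho_inactivation_10s` or
#'   `cho_ssi_family` protocol (one condition).
#' @return List with `percent_inactivated` (per-sweep vector, long-step
#'   protocols) and/or `ssi_points` (data frame `voltage`, `value`).
#' @export
inactivation_metrics <- function(rec) {
  stopifnot(inherits(rec, "kvs_recording"))
  roles <- rec$sweeps[[1]]$epochs$role
  out <- list()
  if ("test" %in% roles && "hold" %in% roles) {
    v <- vapply(rec$sweeps, function(s) {
      s$epochs$voltage[s$epochs$role == "hold"][1]
    }, 0)
    val <- vapply(rec$sweeps, function(s) {
      tr <- .epoch_samples(s, "test")
      mean(tr$i[tr$t >= tr$duration * 0.9])  # late, activation-equilibrated
    }, 0)
    if (max(val) - min(val) <= 0) stop("SSI family has no voltage dependence")
    norm <- (val - min(val)) / (max(val) - min(val))
    pts <- data.frame(voltage = v, value = norm)
    out$ssi_points <- pts[order(pts$voltage), ]
  }
  if ("step" %in% roles) {
    out$percent_inactivated <- vapply(rec$sweeps, function(s) {
      tr <- .epoch_samples(s, "step")
      sm <- stats::filter(tr$i, rep(1 / 5, 5), sides = 2)
      sm[is.na(sm)] <- tr$i[is.na(sm)]
      peak <- max(sm)
      if (peak <= 0) stop("peak current not identifiable")
      iend <- mean(tr$i[tr$t >= tr$duration * 0.98])
      100 * (1 - iend / peak)
    }, 0)
  }
  if (length(out) == 0L) {
    stop("recording contains neither a long step nor an SSI family")
  }
  out
}

#' Apply P/4 leak subtraction to a main sweep
#'
#' Subtracts the scaled, baseline-corrected sum of four quarter-amplitude
#' sub-sweeps (and the main sweep's own holding baseline) from the main
#' sweep. Linear (ohmic) components are removed exactly; channel currents
#' are untouched because the quarter pulses stay below activation voltages.
#'
#' @param main The main `kvs_sweep`.
#' @param subs List of exactly four quarter-amplitude `kvs_sweep`s (from
#'   [p4_sub_sweeps()]).
#' @return The corrected `kvs_sweep` (`p4_subtracted = TRUE`).
#' @export
p4_subtract <- function(main, subs) {
  stopifnot(inherits(main, "kvs_sweep"))
  if (length(subs) != 4L) stop("P/4 subtraction requires exactly 4 sub-sweeps")
  stopifnot(all(vapply(subs, inherits, TRUE, "kvs_sweep")))
  pre_main <- main$epochs$end[1]
  active_main <- which(main$epochs$voltage != main$epochs$voltage[1])
  dv_main <- main$epochs$voltage[active_main[1]] - main$epochs$voltage[1]
  dv_subs <- sum(vapply(subs, function(s) {
    act <- which(s$epochs$voltage != s$epochs$voltage[1])
    s$epochs$voltage[act[1]] - s$epochs$voltage[1]
  }, 0))
  scale <- dv_main / dv_subs
  correction <- Reduce(`+`, lapply(subs, function(s) {
    if (length(s$current) != length(main$current)) {
      stop("sub-sweep length does not match the main sweep")
    }
    pre <- s$epochs$end[1]
    s$current - mean(s$current[s$time < pre])
  }))
  out <- main
  out$current <- main$current - mean(main$current[main$time < pre_main]) -
    scale * correction
  out$p4_subtracted <- TRUE
  out
}
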