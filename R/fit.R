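# Nonlinear least-squares estimation of the activation rise, the Boltzmann
# conductance-voltage relation, bi-exponential deactivation, and the Hill
# concentration-effect model. All fitters use bounded Levenberg-Marquardt
# (minpack.lm) with analytic model evaluation and report diagnostics.

# bounded LM wrapper: returns par, se, converged, rss, n
.ls_fit <- function(start, lower, upper, resid_fn) {
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(start)))
  list(par = fit$par, se = se,
       converged = fit$info %in% 1:4,
       rss = fit$deviance, n = length(resid_fn(fit$par)))
}

.fit_diagnostics <- function(ls, window, flags = character()) {
  structure(list(converged = ls$converged, rss = ls$rss, se = ls$se,
                 window = window, n_points = ls$n, flags = flags),
            class = "fit_diagnostics")
}

# pull samples of one epoch (by role) out of a sweep; t relative to epoch start
.epoch_samples <- function(sweep, role) {
  ep <- sweep$epochs
  row <- which(ep$role == role)
  if (length(row) == 0L) stop("sweep has no epoch with role '", role, "'")
  row <- row[1]
  sel <- sweep$time >= ep$start[row] & sweep$time < ep$end[row]
  list(t = sweep$time[sel] - ep$start[row], i = sweep$current[sel],
       start_abs = ep$start[row], duration = ep$duration[row],
       voltage = ep$voltage[row])
}

#' Fit the power-exponential activation time course to a current rise
#'
#' Fits `A * (1 - exp(-(t - t0)/tau))^sigma` to the 10--90% portion of the
#' rise within the step epoch. The baseline is estimated from the earliest
#' samples of the epoch and the plateau from its final 10%; the fit origin is
#' shifted `t0_offset` ms after the step start (the conventional correction
#' for filter delay, which synthetic sweeps do not have -- pass 0 for them).
#' The baseline estimate is subtracted before fitting.
#'
#' @param sweep A `kvs_sweep`, or a list with `t` (ms from step onset) and
#'   `i` (pA).
#' @param t0_offset Origin shift in ms.
#' @param role Epoch role holding the rise (when `sweep` is a `kvs_sweep`).
#' @return List with `fit` (an [activation_fit()]) and `diagnostics`.
#' @export
fit_activation <- function(sweep, t0_offset = 0.1, role = "step") {
  tr <- if (inherits(sweep, "kvs_sweep")) .epoch_samples(sweep, role) else sweep
  t <- tr$t; i <- tr$i
  n <- length(t)
  if (n < 30L) stop("too few samples in step epoch")
  # baseline: the pre-step holding segment when available (continuous with
  # the step start), otherwise the first few samples of the epoch
  baseline <- if (inherits(sweep, "kvs_sweep") &&
                  "pre_hold" %in% sweep$epochs$role) {
    mean(.epoch_samples(sweep, "pre_hold")$i)
  } else {
    i[1]  # value at step onset
  }
  plateau <- mean(i[t >= max(t) * 0.9])
  span <- plateau - baseline
  if (!is.finite(span) || span <= 0 ||
      abs(span) <= 1e-12 * max(abs(i), 1e-12) ||
      span < 4 * stats::sd(i[seq_len(max(3L, ceiling(0.01 * n)))]) + 1e-12) {
    stop("no rise detected in step epoch")
  }
  t10 <- t[which(i >= baseline + 0.1 * span)[1]]
  t90 <- t[which(i >= baseline + 0.9 * span)[1]]
  sel <- t >= t10 & t <= t90
  if (sum(sel) < 20L) stop("fewer than 20 samples in the 10-90% rise window")
  tw <- t[sel] - t0_offset
  iw <- i[sel] - baseline
  t63 <- t[which(i >= baseline + 0.632 * span)[1]]
  start <- c(A = span, tau = max(t63, 1e-3), sigma = 1)
  resid_fn <- function(p) {
    p["A"] * (1 - exp(-pmax(tw, 0) / p["tau"]))^p["sigma"] - iw
  }
  ls <- .ls_fit(start, lower = c(0, 0.01, 0.1), upper = c(Inf, 1e4, 20),
                resid_fn)
  fit <- activation_fit(amplitude = unname(ls$par["A"]),
                        tau_act = unname(ls$par["tau"]),
                        sigma = unname(ls$par["sigma"]),
                        t0_offset = t0_offset)
  list(fit = fit, diagnostics = .fit_diagnostics(ls, window = c(t10, t90)))
}

#' Fit a Boltzmann function to conductance-voltage points
#'
#' Estimates amplitude, half-maximal voltage and gating charge by bounded
#' least squares at the configured temperature. For steady-state inactivation
#' data that were normalized to their own maximum and minimum, set
#' `minmax = TRUE`: the model curve is then min-max normalized over the data
#' voltages before comparison (the amplitude is not a free parameter), which
#' keeps the half-voltage estimate consistent with the normalization.
#'
#' @param points Data frame with columns `voltage` (mV) and `value`
#'   (conductance or normalized current).
#' @param direction `"activation"` or `"inactivation"`.
#' @param minmax Model min-max normalization (for SSI input)?
#' @param const [phys_constants()].
#' @return List with `fit` (a [boltzmann_params()]) and `diagnostics`.
#' @export
fit_boltzmann <- function(points, direction = c("activation", "inactivation"),
                          minmax = FALSE, const = phys_constants()) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(points),
            all(c("voltage", "value") %in% names(points)))
  points <- points[order(points$voltage), ]
  v <- points$voltage; y <- points$value
  if (length(v) < 4L) stop("insufficient points for a Boltzmann fit (need >= 4)")
  ymax <- max(y); ymin <- min(y)
  flags <- character()
  if (ymax - ymin < 0.25 * max(abs(ymax), 1e-12)) {
    flags <- c(flags, "non_identifiable: points span a single plateau")
  }
  half <- ymin + 0.5 * (ymax - ymin)
  v_half0 <- v[which.min(abs(y - half))]
  model <- function(p) {
    bp <- boltzmann_params(amplitude = if (minmax) 1 else unname(p["A"]),
                           v_half = unname(p["v_half"]), z = unname(p["z"]),
                           direction = direction)
    f <- boltzmann(v, bp, const)
    if (minmax) f <- (f - min(f)) / (max(f) - min(f))
    f
  }
  if (minmax) {
    start <- c(v_half = v_half0, z = 2)
    ls <- .ls_fit(start, lower = c(-Inf, 0.1), upper = c(Inf, 10),
                  function(p) model(p) - y)
    amp <- 1
  } else {
    start <- c(A = ymax, v_half = v_half0, z = 2)
    ls <- .ls_fit(start, lower = c(0, -Inf, 0.1), upper = c(Inf, Inf, 10),
                  function(p) model(p) - y)
    amp <- unname(ls$par["A"])
  }
  fit <- boltzmann_params(amplitude = amp,
                          v_half = unname(ls$par["v_half"]),
                          z = unname(ls$par["z"]), direction = direction)
  list(fit = fit,
       diagnostics = .fit_diagnostics(ls, window = range(v), flags = flags))
}

#' Fit bi-exponential deactivation to a tail current
#'
#' The fit window runs from the tail-current peak (located on a 5-sample
#' moving average within the first 20 ms; fitting uses raw samples) to
#' `fit_end_ms` after the voltage step. `mode = "monoexp"` constrains the
#' second amplitude to zero. Components are returned fast-first; if the two
#' time constants collapse (within 1%) the equivalent mono-exponential fit is
#' returned and flagged.
#'
#' @param sweep A `kvs_sweep` (tail epoch used) or a list with `t` (ms from
#'   tail onset) and `i` (pA).
#' @param mode `"biexp"` or `"monoexp"`.
#' @param fit_end_ms Window end, ms after the voltage step.
#' @param role Epoch role holding the tail.
#' @return List with `fit` (a [biexp_fit()]) and `diagnostics`.
#' @export
fit_deactivation <- function(sweep, mode = c("biexp", "monoexp"),
                             fit_end_ms = 200, role = "tail") {
  mode <- match.arg(mode)
  tr <- if (inherits(sweep, "kvs_sweep")) .epoch_samples(sweep, role) else sweep
  t <- tr$t; i <- tr$i
  if (length(t) < 20L) stop("too few samples in tail epoch")
  sm <- stats::filter(i, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- i[is.na(sm)]
  search <- which(t <= 20)
  peak_idx <- search[which.max(abs(sm[search] - mean(i[t >= max(t) * 0.95])))]
  if (peak_idx >= length(t)) stop("tail peak located at the final sample")
  sel <- seq(peak_idx, max(which(t <= fit_end_ms)))
  if (length(sel) < 10L) stop("tail fit window too short")
  t0 <- t[peak_idx]
  tw <- t[sel] - t0
  iw <- i[sel]
  y0_0 <- mean(iw[tw >= max(tw) * 0.95])
  span <- iw[1] - y0_0
  if (abs(span) <= max(1e-10, 1e-6 * max(abs(iw)))) {
    stop("no relaxation detected in tail epoch")
  }
  fit_mono <- function() {
    start <- c(y0 = y0_0, A1 = span, tau1 = max(tw)[1] / 5)
    ls <- .ls_fit(start, lower = c(-Inf, -Inf, 0.01),
                  upper = c(Inf, Inf, 1e4),
                  function(p) p["y0"] + p["A1"] * exp(-tw / p["tau1"]) - iw)
    list(ls = ls,
         fit = biexp_fit(y0 = unname(ls$par["y0"]),
                         a1 = unname(ls$par["A1"]),
                         tau1 = unname(ls$par["tau1"]), a2 = 0, t0 = t0))
  }
  if (mode == "monoexp") {
    m <- fit_mono()
    return(list(fit = m$fit,
                diagnostics = .fit_diagnostics(m$ls, window = c(t0, t0 + max(tw)))))
  }
  start <- c(y0 = y0_0, A1 = 0.7 * span, tau1 = max(tw) / 10,
             A2 = 0.3 * span, tau2 = max(tw) / 2)
  ls <- .ls_fit(start, lower = c(-Inf, -Inf, 0.01, -Inf, 0.01),
                upper = c(Inf, Inf, 1e4, Inf, 1e4),
                function(p) p["y0"] + p["A1"] * exp(-tw / p["tau1"]) +
                  p["A2"] * exp(-tw / p["tau2"]) - iw)
  tau1 <- unname(ls$par["tau1"]); tau2 <- unname(ls$par["tau2"])
  flags <- character()
  if (abs(tau1 - tau2) / max(tau1, tau2) < 0.01) {
    m <- fit_mono()
    return(list(fit = m$fit,
                diagnostics = .fit_diagnostics(
                  m$ls, window = c(t0, t0 + max(tw)),
                  flags = "tau_collapse: equivalent mono-exponential returned")))
  }
  fit <- biexp_fit(y0 = unname(ls$par["y0"]), a1 = unname(ls$par["A1"]),
                   tau1 = tau1, a2 = unname(ls$par["A2"]), tau2 = tau2,
                   t0 = t0)
  list(fit = fit,
       diagnostics = .fit_diagnostics(ls, window = c(t0, t0 + max(tw)),
                                      flags = flags))
}

#' Fit the Hill concentration-effect model
#'
#' Fits `base + (1 - base)/(1 + (c/IC50)^nH)` (top fixed at 1) to responses
#' expressed as fractions of a reference measurement. When the responses were
#' normalized to the measurement at a reference concentration (the usual
#' pre-block convention), pass that concentration as `reference_conc`: the
#' model is then evaluated relative to its own value at the reference, which
#' keeps the IC50 estimate consistent with the normalization.
#'
#' @param concs Concentrations (nM).
#' @param responses Normalized responses (fraction of reference).
#' @param fix_n_hill Fix the Hill coefficient at this value (default 1); use
#'   `NULL` to fit it freely.
#' @param reference_conc Concentration (nM) the responses were normalized
#'   at, or `NULL` if they are absolute fractions of the unblocked current.
#' @return List with `fit` (a [hill_fit()]) and `diagnostics`.
#' @export
fit_hill <- function(concs, responses, fix_n_hill = 1,
                     reference_conc = NULL) {
  stopifnot(length(concs) == length(responses))
  if (length(unique(concs)) < 3L) {
    stop("at least 3 distinct concentrations are required")
  }
  if (any(concs <= 0)) stop("concentrations must be > 0")
  flags <- character()
  if (diff(range(responses)) < 0.05 * max(abs(responses))) {
    flags <- c(flags, "non_identifiable: responses nearly constant")
  }
  free_n <- is.null(fix_n_hill)
  model <- function(p) {
    nh <- if (free_n) unname(p["n"]) else fix_n_hill
    h <- function(cc) p["base"] + (1 - p["base"]) / (1 + (cc / p["ic50"])^nh)
    f <- h(concs)
    if (!is.null(reference_conc)) f <- f / h(reference_conc)
    unname(f)
  }
  start <- c(ic50 = exp(mean(log(concs))), base = 0.05)
  lower <- c(1e-6, 0); upper <- c(Inf, 0.999)
  if (free_n) {
    start <- c(start, n = 1)
    lower <- c(lower, 0.1); upper <- c(upper, 10)
  }
  ls <- .ls_fit(start, lower, upper, function(p) model(p) - responses)
  fit <- hill_fit(ic50 = unname(ls$par["ic50"]),
                  n_hill = if (free_n) unname(ls$par["n"]) else fix_n_hill,
                  base = min(unname(ls$par["base"]), 1 - 1e-12))
  list(fit = fit,
       diagnostics = .fit_diagnostics(ls, window = range(concs),
                                      flags = flags))
}

#' Arithmetic or geometric summary of replicate values
#'
#' Linear scale reports the arithmetic mean and SEM. Log scale reports the
#' geometric mean `exp(mean(ln x))` with the SEM propagated in natural-log
#' space (the convention for time-constant statistics).
#'
#' @param values Numeric vector; must be positive for `scale = "log"`.
#' @param scale `"linear"` or `"log"`.
#' @return List with `estimate`, `sem` (on the reported scale), `n`, `scale`
#'   and, for log scale, `log_sem`.
#' @export
summarize_values <- function(values, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  n <- length(values)
  if (scale == "linear") {
    list(estimate = mean(values),
         sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
         n = n, scale = scale)
  } else {
    if (any(values <= 0)) stop("log-scale summary requires positive values")
    lx <- log(values)
    gm <- exp(mean(lx))
    log_sem <- if (n > 1) stats::sd(lx) / sqrt(n) else NA_real_
    list(estimate = gm, sem = gm * log_sem, n = n, scale = scale,
         log_sem = log_sem)
  }
}
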