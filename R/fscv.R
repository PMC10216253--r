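# Electrically evoked dopamine release and uptake: Michaelis-Menten trace
# simulation and fitting, stimulation protocols (intensity series, 4-pulse
# frequency trains), electrode calibration and nicotine modulation curves.

#' Michaelis-Menten release/uptake parameters
#'
#' Kinetic parameters of evoked dopamine transients: each stimulus pulse
#' releases `da_per_pulse` uM of dopamine essentially instantaneously
#' (pulse widths of a few ms are far below the trace resolution), and
#' clearance follows Michaelis-Menten transporter kinetics
#' `d[DA]/dt = -vmax [DA] / (km + [DA])`. `km` is conventionally fixed
#' (default 0.16 uM, the common striatal dopamine uptake affinity) because
#' `vmax` and `km` are poorly jointly identifiable from single transients.
#'
#' @param vmax Maximal uptake rate, uM/s.
#' @param km Uptake affinity constant, uM.
#' @param da_per_pulse Dopamine released per stimulus pulse, uM.
#' @return An object of class `mm_params`.
#' @export
mm_params <- function(vmax, km = 0.16, da_per_pulse) {
  if (any(c(vmax, km, da_per_pulse) <= 0) ||
      any(!is.finite(c(vmax, km, da_per_pulse))))
    stop("mm_params: vmax, km and da_per_pulse must be strictly positive",
         call. = FALSE)
  structure(list(vmax = vmax, km = km, da_per_pulse = da_per_pulse),
            class = "mm_params")
}

#' Electrical stimulation pattern
#'
#' A single pulse or an evenly spaced pulse train. The standard single
#' pulse is 7.5 V input / 350 uA output, 4 ms, monophasic; trains are
#' four-pulse at 3, 10, 30 or 100 Hz in the frequency-response protocol.
#'
#' @param n_pulses Number of pulses.
#' @param frequency Train frequency, Hz (required when `n_pulses > 1`).
#' @param onset_s Time of the first pulse, s.
#' @param intensity_v Stimulation input intensity, V.
#' @param intensity_ua Stimulation output, uA.
#' @param pulse_width_ms Pulse width, ms.
#' @return An object of class `stim_pattern` with computed `pulse_times`.
#' @export
stim_pattern <- function(n_pulses = 1, frequency = NULL, onset_s = 0.5,
                         intensity_v = 7.5, intensity_ua = 350,
                         pulse_width_ms = 4) {
  if (n_pulses < 1 || n_pulses != round(n_pulses))
    stop("stim_pattern: 'n_pulses' must be a positive integer",
         call. = FALSE)
  if (n_pulses > 1 && (is.null(frequency) || frequency <= 0))
    stop("stim_pattern: a positive 'frequency' is required for trains",
         call. = FALSE)
  pulse_times <- if (n_pulses == 1) onset_s
                 else onset_s + (seq_len(n_pulses) - 1) / frequency
  structure(list(n_pulses = as.integer(n_pulses), frequency = frequency,
                 onset_s = onset_s, pulse_times = pulse_times,
                 intensity_v = intensity_v, intensity_ua = intensity_ua,
                 pulse_width_ms = pulse_width_ms),
            class = "stim_pattern")
}

#' Dopamine concentration trace
#'
#' Uniformly sampled dopamine concentration versus time, with the
#' stimulation pattern attached.
#'
#' @param time_s Uniform time grid, s.
#' @param da_um Dopamine concentration, uM.
#' @param stim Optional [stim_pattern()].
#' @return A data frame of class `fscv_trace`.
#' @export
fscv_trace <- function(time_s, da_um, stim = NULL) {
  if (length(time_s) != length(da_um))
    stop("fscv_trace: time and concentration lengths differ", call. = FALSE)
  if (length(time_s) > 2L) {
    dts <- diff(time_s)
    if (max(dts) - min(dts) > 1e-9 * max(dts))
      stop("fscv_trace: time grid must be uniform", call. = FALSE)
  }
  out <- data.frame(time_s = time_s, da_um = da_um)
  attr(out, "stim") <- stim
  class(out) <- c("fscv_trace", "data.frame")
  out
}

# integrate MM decay from C0 over relative times ts (ts[1] == 0)
.mm_decay <- function(c0, vmax, km, ts) {
  if (c0 <= 0 || length(ts) == 1L) return(rep(max(c0, 0), length(ts)))
  sol <- deSolve::lsoda(c(C = c0), ts,
                        function(t, y, p) list(-vmax * y[1] / (km + y[1])),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  pmax(sol[, "C"], 0)
}

#' Simulate an evoked dopamine transient
#'
#' Integrates Michaelis-Menten clearance with an instantaneous
#' `da_per_pulse` increment at each stimulus pulse, starting from zero
#' dopamine. The output grid is uniform with spacing `dt`; for pulse
#' trains, `dt` must resolve the train (at most half the inter-pulse
#' interval).
#'
#' @param params An [mm_params()] object.
#' @param stim A [stim_pattern()].
#' @param duration Trace duration, s.
#' @param dt Sampling interval, s (default 0.1 s, the conventional 10
#'   waveform repetitions per second).
#' @return An [fscv_trace()].
#' @export
#' @examples
#' tr <- simulate_trace(mm_params(vmax = 2, da_per_pulse = 1),
#'                      stim_pattern(), duration = 3)
#' peak_da(tr)
simulate_trace <- function(params, stim, duration = 5, dt = 0.1) {
  stopifnot(inherits(params, "mm_params"), inherits(stim, "stim_pattern"))
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (stim$n_pulses > 1 && dt > 1 / (2 * stim$frequency))
    stop(sprintf(
      "dt = %g s is too coarse to resolve a %g Hz train (need <= %g s)",
      dt, stim$frequency, 1 / (2 * stim$frequency)), call. = FALSE)
  pulses <- stim$pulse_times
  if (any(pulses < 0) || any(pulses > duration))
    stop("pulse times must lie within [0, duration]", call. = FALSE)
  grid <- seq(0, duration, by = dt)
  bounds <- sort(unique(c(0, pulses, duration)))
  y <- 0
  da <- numeric(length(grid))
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]
    b <- bounds[i + 1L]
    if (any(abs(pulses - a) < 1e-12)) y <- y + params$da_per_pulse
    sel <- which(grid >= a - 1e-12 & grid < b - 1e-12)
    ts <- c(a, grid[sel], b)
    rel <- ts - a
    vals <- .mm_decay(y, params$vmax, params$km, unique(rel))
    vals <- vals[match(rel, unique(rel))]
    if (length(sel)) da[sel] <- vals[seq_along(sel) + 1L]
    y <- vals[length(vals)]
  }
  if (abs(grid[length(grid)] - duration) < 1e-12) {
    if (any(abs(pulses - duration) < 1e-12)) y <- y + params$da_per_pulse
    da[length(grid)] <- y
  }
  fscv_trace(grid, da, stim)
}

#' Peak dopamine concentration
#'
#' Maximum concentration and its time within a post-stimulus window
#' (defaulting to the first pulse onward, or the whole trace when no
#' stimulation is attached).
#'
#' @param trace An [fscv_trace()].
#' @param window Optional two-element window, s.
#' @return Named list `peak_um`, `peak_time_s`.
#' @export
peak_da <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "fscv_trace"))
  stim <- attr(trace, "stim")
  if (is.null(window)) {
    lo <- if (!is.null(stim)) min(stim$pulse_times) else min(trace$time_s)
    window <- c(lo, max(trace$time_s))
  }
  sel <- trace$time_s >= window[1] - 1e-12 & trace$time_s <= window[2] + 1e-12
  if (!any(sel)) stop("empty peak window", call. = FALSE)
  y <- trace$da_um[sel]
  t <- trace$time_s[sel]
  i <- which.max(y)
  list(peak_um = y[i], peak_time_s = t[i])
}

#' Fit Michaelis-Menten kinetics to an evoked transient
#'
#' Least-squares estimation of `vmax` and `da_per_pulse` (with `km` fixed)
#' by matching the simulated transient to the recorded trace on its own
#' grid. The search runs on log-parameters from several starts.
#'
#' @param trace An [fscv_trace()] containing a stimulus-aligned transient.
#' @param stim The [stim_pattern()] used (defaults to the one attached to
#'   the trace).
#' @param km Fixed uptake affinity, uM.
#' @return List of class `mm_fit`: `params` (an [mm_params()]), `rss`,
#'   `peak_um`, `converged`.
#' @export
#' @examples
#' p <- mm_params(vmax = 2, da_per_pulse = 1)
#' tr <- simulate_trace(p, stim_pattern(), duration = 3)
#' fit_mm(tr)$params$vmax  # recovers 2
fit_mm <- function(trace, stim = NULL, km = 0.16) {
  stopifnot(inherits(trace, "fscv_trace"))
  if (is.null(stim)) stim <- attr(trace, "stim")
  if (is.null(stim))
    stop("no stimulation pattern available for fitting", call. = FALSE)
  y <- trace$da_um
  t <- trace$time_s
  if (max(y) <= 1e-9)
    stop("no signal: trace contains no positive dopamine transient",
         call. = FALSE)
  dt <- t[2] - t[1]
  duration <- max(t)
  peak0 <- max(y)
  dap0 <- max(peak0 / max(stim$n_pulses / 2, 1), 1e-3)
  obj <- function(p) {
    par <- exp(p)
    sim <- simulate_trace(mm_params(vmax = par[1], km = km,
                                    da_per_pulse = par[2]),
                          stim, duration = duration, dt = dt)
    sum((sim$da_um - y)^2)
  }
  starts <- list(c(log(0.5), log(dap0)), c(log(2), log(dap0)),
                 c(log(8), log(dap0)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, obj, method = "Nelder-Mead",
                               control = list(reltol = 1e-12,
                                              maxit = 2000)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop("Michaelis-Menten fit did not converge", call. = FALSE)
  par <- exp(best$par)
  structure(list(params = mm_params(vmax = par[1], km = km,
                                    da_per_pulse = par[2]),
                 rss = best$value, peak_um = peak0,
                 converged = best$convergence == 0),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "MM fit: vmax = %.4g uM/s, [DA]p = %.4g uM (km fixed at %.3g uM), rss %.3g\n",
    x$params$vmax, x$params$da_per_pulse, x$params$km, x$rss))
  invisible(x)
}

#' Stimulation-intensity curve
#'
#' Peak evoked dopamine per single-pulse stimulation intensity, plus the
#' curve normalized to its own maximum.
#'
#' @param traces List of [fscv_trace()] objects, one per intensity.
#' @param intensities Stimulation intensities, V (distinct; defaults to
#'   each trace's attached stimulation intensity).
#' @return Data frame of class `intensity_curve`: `intensity_v`, `peak_um`,
#'   `normalized`.
#' @export
intensity_curve <- function(traces, intensities = NULL) {
  if (is.null(intensities))
    intensities <- vapply(traces, function(tr) attr(tr, "stim")$intensity_v,
                          numeric(1))
  if (length(traces) != length(intensities))
    stop("one trace per intensity required", call. = FALSE)
  if (anyDuplicated(intensities))
    stop("duplicate stimulation intensities", call. = FALSE)
  peaks <- vapply(traces, function(tr) peak_da(tr)$peak_um, numeric(1))
  o <- order(intensities)
  out <- data.frame(intensity_v = intensities[o], peak_um = peaks[o],
                    normalized = peaks[o] / max(peaks))
  class(out) <- c("intensity_curve", "data.frame")
  out
}

#' Frequency-response curve for pulse trains
#'
#' Peak dopamine for four-pulse trains at each frequency, expressed both in
#' uM and as a percentage of the single-pulse evoked release.
#'
#' @param single_pulse_trace Reference single-pulse [fscv_trace()].
#' @param train_traces List of train traces, one per frequency.
#' @param frequencies Train frequencies, Hz (defaults to the attached
#'   stimulation frequencies).
#' @return Data frame of class `frequency_curve`: `frequency_hz`,
#'   `peak_um`, `percent_single_pulse`.
#' @export
frequency_response <- function(single_pulse_trace, train_traces,
                               frequencies = NULL) {
  if (is.null(single_pulse_trace))
    stop("a single-pulse reference trace is required", call. = FALSE)
  if (is.null(frequencies))
    frequencies <- vapply(train_traces,
                          function(tr) attr(tr, "stim")$frequency,
                          numeric(1))
  ref <- peak_da(single_pulse_trace)$peak_um
  if (ref <= 0)
    stop("single-pulse reference release must be positive", call. = FALSE)
  peaks <- vapply(train_traces, function(tr) peak_da(tr)$peak_um, numeric(1))
  o <- order(frequencies)
  out <- data.frame(frequency_hz = frequencies[o], peak_um = peaks[o],
                    percent_single_pulse = 100 * peaks[o] / ref)
  class(out) <- c("frequency_curve", "data.frame")
  out
}

#' Electrode calibration regression
#'
#' Ordinary least-squares regression of dopamine sensitivity (nA per uM) on
#' electrode background-current features, used to convert recorded current
#' to concentration for electrodes that were not individually calibrated.
#' Any feature columns are accepted; the default workflow uses a single
#' regressor (peak background current).
#'
#' @param table Data frame with one or more feature columns plus the
#'   response column.
#' @param response Name of the sensitivity column.
#' @return Object of class `calibration_model` wrapping the [stats::lm()]
#'   fit.
#' @export
calibrate_electrode <- function(table, response = "sensitivity_na_per_um") {
  if (!response %in% names(table))
    stop("calibration table lacks the '", response, "' column",
         call. = FALSE)
  features <- setdiff(names(table), response)
  if (!length(features))
    stop("calibration table needs at least one feature column",
         call. = FALSE)
  if (nrow(table) < length(features) + 2L)
    stop("calibration needs at least p + 2 rows for p features",
         call. = FALSE)
  fml <- stats::as.formula(paste(response, "~",
                                 paste(features, collapse = " + ")))
  fit <- stats::lm(fml, data = table)
  if (anyNA(stats::coef(fit)))
    stop("collinear (rank-deficient) calibration features", call. = FALSE)
  if (any(stats::fitted(fit) <= 0))
    warning("calibration model predicts non-positive sensitivity over the ",
            "training range")
  structure(list(model = fit, features = features, response = response),
            class = "calibration_model")
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  unname(stats::predict(object$model, newdata = newdata))
}

#' Convert a raw current trace to concentration
#'
#' Applies a calibrated sensitivity (nA per uM) predicted from an
#' electrode's background-current features: concentration = current /
#' sensitivity.
#'
#' @param time_s Uniform time grid, s.
#' @param current_na Recorded current, nA.
#' @param model A [calibrate_electrode()] model.
#' @param features One-row data frame of the electrode's feature values.
#' @param stim Optional [stim_pattern()] to attach.
#' @return An [fscv_trace()] in uM.
#' @export
apply_calibration <- function(time_s, current_na, model, features,
                              stim = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  s <- predict(model, features)
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    stop("predicted sensitivity must be a single positive value",
         call. = FALSE)
  fscv_trace(time_s, current_na / s, stim)
}

#' Nicotine modulation of evoked release
#'
#' Normalizes evoked dopamine release at increasing nicotine bath
#' concentrations to the drug-free baseline release (baseline = 1) and fits
#' an inhibition Hill model, yielding a per-slice IC50. A flat curve (all
#' doses within `flat_tol` of baseline) is flagged instead of fitted.
#'
#' @param baseline_peak Drug-free evoked release (uM), > 0.
#' @param doses_molar Nicotine bath concentrations, molar, increasing.
#' @param peaks Evoked release at each dose, uM.
#' @param flat_tol Relative deviation below which the curve is called flat.
#' @return List: `flat` (logical), `series` (the normalized
#'   [dose_response_series()]), `fit` (a `hill_fit` or NULL), `ic50`.
#' @export
nicotine_modulation_curve <- function(baseline_peak, doses_molar, peaks,
                                      flat_tol = 0.02) {
  if (!is.finite(baseline_peak) || baseline_peak <= 0)
    stop("baseline release must be positive", call. = FALSE)
  if (any(diff(doses_molar) <= 0))
    stop("doses must be strictly increasing", call. = FALSE)
  rel <- peaks / baseline_peak
  if (all(abs(rel - 1) <= flat_tol))
    return(list(flat = TRUE, series = NULL, fit = NULL, ic50 = NA_real_))
  series <- dose_response_series(doses_molar, rel, replicate = 1L)
  fit <- fit_hill(series, direction = "inhibition")
  list(flat = FALSE, series = series, fit = fit, ic50 = fit$ec50)
}
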