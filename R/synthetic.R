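# Synthetic cohorts, dose-response replicates and dopamine traces with the
# statistical structure the analyses assume, plus ground-truth manifests
# for parameter-recovery testing.

#' Behavioural generating model for one group
#'
#' Configuration of the session generator: a loading phase (a burst of
#' infusions early in the session), a maintenance phase with log-normal
#' inter-infusion intervals (the heavy right tail matches post-infusion
#' pausing), an across-day multiplicative trend on the infusion rate
#' (escalation when > 1, extinction when < 1), Poisson inactive poking and
#' Poisson extra active poking during timeouts.
#'
#' @param group Group label.
#' @param dose_ug_per_kg Unit dose, ug/kg (0 for saline).
#' @param loading_n Number of loading infusions.
#' @param loading_window_min Window containing the loading infusions, min.
#' @param maint_interval_mean_min Mean maintenance inter-infusion interval,
#'   min.
#' @param maint_interval_cv Coefficient of variation of the intervals.
#' @param day_multiplier Per-day multiplicative trend on the infusion rate.
#' @param inactive_rate_per_min Poisson rate of inactive pokes, events/min.
#' @param timeout_poke_rate_per_s Poisson rate of non-counting active pokes
#'   during each post-infusion timeout, events/s.
#' @param fr Fixed-ratio requirement.
#' @param timeout_s Post-infusion timeout, s.
#' @param session_min Session length, min.
#' @return A list of class `behavioral_config`.
#' @export
behavioral_config <- function(group = "standard_dose", dose_ug_per_kg = 30,
                              loading_n = 10, loading_window_min = 18,
                              maint_interval_mean_min = 8,
                              maint_interval_cv = 0.35,
                              day_multiplier = 1,
                              inactive_rate_per_min = 0.05,
                              timeout_poke_rate_per_s = 0.01,
                              fr = 1, timeout_s = 20, session_min = 120) {
  if (inactive_rate_per_min < 0 || timeout_poke_rate_per_s < 0 ||
      maint_interval_cv < 0 || loading_n < 0)
    stop("behavioral_config: rates and counts must be non-negative",
         call. = FALSE)
  if (day_multiplier <= 0)
    stop("behavioral_config: 'day_multiplier' must be positive",
         call. = FALSE)
  min_gap_s <- timeout_s + fr + 1
  if (maint_interval_mean_min * 60 <= min_gap_s)
    stop("behavioral_config: infeasible - the mean inter-infusion ",
         "interval must exceed the timeout plus the FR poke train (",
         min_gap_s, " s)", call. = FALSE)
  structure(list(group = group, dose_ug_per_kg = dose_ug_per_kg,
                 loading_n = loading_n,
                 loading_window_min = loading_window_min,
                 maint_interval_mean_min = maint_interval_mean_min,
                 maint_interval_cv = maint_interval_cv,
                 day_multiplier = day_multiplier,
                 inactive_rate_per_min = inactive_rate_per_min,
                 timeout_poke_rate_per_s = timeout_poke_rate_per_s,
                 fr = fr, timeout_s = timeout_s, session_min = session_min),
            class = "behavioral_config")
}

# enforce a minimum spacing (seconds) on sorted times, dropping overflow
.space_out <- function(t, min_gap, t_max) {
  t <- sort(t)
  for (i in seq_along(t)[-1]) {
    if (t[i] < t[i - 1] + min_gap) t[i] <- t[i - 1] + min_gap
  }
  t[t <= t_max]
}

#' Generate one synthetic self-administration session
#'
#' Constructs an event log that obeys the fixed-ratio / timeout semantics
#' exactly: each scheduled infusion is preceded by exactly `fr` counting
#' active pokes placed immediately before it, extra non-counting active
#' pokes fall inside post-infusion timeouts, and inactive pokes are
#' homogeneous Poisson. Uses the caller's RNG state (seed with
#' [set.seed()] for reproducibility).
#'
#' @param config A [behavioral_config()].
#' @param day Session day index (drives the across-day trend).
#' @param subject_id Subject identifier.
#' @param rate_scale Extra multiplicative factor on the infusion rate
#'   (e.g. per-subject variability).
#' @param group Optional group label stored on the log.
#' @return A [session_log()] that passes [validate_schedule_semantics()]
#'   with zero violations.
#' @export
#' @examples
#' set.seed(1)
#' log <- generate_session(behavioral_config(), day = 1)
#' nrow(validate_schedule_semantics(log))  # 0
generate_session <- function(config, day = 1, subject_id = "S1",
                             rate_scale = 1, group = config$group) {
  stopifnot(inherits(config, "behavioral_config"))
  session_s <- config$session_min * 60
  min_gap <- config$timeout_s + config$fr + 1
  m <- config$day_multiplier^(day - 1) * rate_scale

  # loading burst: jittered even spacing inside the loading window
  n_load <- round(config$loading_n * min(1, m))
  load_t <- numeric(0)
  if (n_load > 0) {
    w <- config$loading_window_min * 60
    centers <- w * (seq_len(n_load) - 0.5) / n_load
    jitter <- stats::runif(n_load, -0.2, 0.2) * w / n_load
    load_t <- pmax(centers + jitter, config$fr + 1)
    load_t <- .space_out(load_t, min_gap, session_s - 1)
  }

  # maintenance: log-normal inter-infusion intervals, rate scaled by m
  mean_s <- config$maint_interval_mean_min * 60 / m
  sigma <- sqrt(log(1 + config$maint_interval_cv^2))
  mu <- log(mean_s) - sigma^2 / 2
  t <- if (length(load_t)) max(load_t) else config$fr + 1
  maint_t <- numeric(0)
  repeat {
    gap <- max(stats::rlnorm(1, mu, sigma), min_gap)
    t <- t + gap
    if (t > session_s - 1) break
    maint_t <- c(maint_t, t)
  }
  inf_t <- .space_out(c(load_t, maint_t), min_gap, session_s - 1)

  # counting active pokes: fr pokes ending exactly at each infusion
  act_t <- unlist(lapply(inf_t, function(ti) ti - (config$fr - 1):0))
  # non-counting active pokes inside timeouts
  extra_t <- unlist(lapply(inf_t, function(ti) {
    k <- stats::rpois(1, config$timeout_poke_rate_per_s * config$timeout_s)
    if (k == 0) return(numeric(0))
    stats::runif(k, ti + 0.5, ti + config$timeout_s - 0.5)
  }))
  extra_t <- extra_t[extra_t <= session_s]
  # inactive pokes: homogeneous Poisson over the session
  n_inact <- stats::rpois(1, config$inactive_rate_per_min * config$session_min)
  inact_t <- sort(stats::runif(n_inact, 0, session_s))

  events <- rbind(
    data.frame(t_sec = act_t,
               kind = rep("active", length(act_t))),
    data.frame(t_sec = extra_t,
               kind = rep("active", length(extra_t))),
    data.frame(t_sec = inact_t,
               kind = rep("inactive", length(inact_t))),
    data.frame(t_sec = inf_t,
               kind = rep("infusion", length(inf_t))))
  # order by time with pokes before coincident infusions
  events <- events[order(events$t_sec,
                         match(events$kind, c("active", "inactive",
                                              "infusion"))), , drop = FALSE]
  session_log(subject_id = subject_id, day = day, events = events,
              dose_ug_per_kg = config$dose_ug_per_kg, fr = config$fr,
              timeout_s = config$timeout_s, session_min = config$session_min,
              group = group)
}

# group-level generating configurations for the named scenarios
scenario_defaults <- function(scenario) {
  switch(scenario,
    standard_dose = list(
      config = behavioral_config("standard_dose", dose_ug_per_kg = 30,
                                 loading_n = 10, loading_window_min = 18,
                                 maint_interval_mean_min = 8),
      n_subjects = 7, n_days = 10, classifier = "standard"),
    cre_pos_lowdose = list(
      config = behavioral_config("cre_pos_lowdose", dose_ug_per_kg = 1.5,
                                 loading_n = 3, loading_window_min = 20,
                                 maint_interval_mean_min = 6),
      n_subjects = 14, n_days = 10, classifier = "lowdose"),
    cre_neg_lowdose = list(
      config = behavioral_config("cre_neg_lowdose", dose_ug_per_kg = 1.5,
                                 loading_n = 2, loading_window_min = 20,
                                 maint_interval_mean_min = 16,
                                 day_multiplier = 0.95),
      n_subjects = 8, n_days = 10, classifier = "lowdose"),
    naive_lowdose = list(
      config = behavioral_config("naive_lowdose", dose_ug_per_kg = 1.5,
                                 loading_n = 1, loading_window_min = 20,
                                 maint_interval_mean_min = 25,
                                 day_multiplier = 0.92),
      n_subjects = 9, n_days = 10, classifier = "lowdose"),
    thcre = list(
      config = behavioral_config("thcre", dose_ug_per_kg = 1.5,
                                 loading_n = 3, loading_window_min = 20,
                                 maint_interval_mean_min = 7),
      control_config = behavioral_config("non_tg", dose_ug_per_kg = 1.5,
                                         loading_n = 1,
                                         loading_window_min = 20,
                                         maint_interval_mean_min = 40,
                                         day_multiplier = 0.95),
      n_subjects = 11, n_controls = 6, n_days = 17,
      escalation_day = 10, escalation_rate = 1.13,
      classifier = "control_referenced"),
    saline_substitution = list(
      config = behavioral_config("saline_substitution",
                                 dose_ug_per_kg = 1.5, loading_n = 3,
                                 loading_window_min = 20,
                                 maint_interval_mean_min = 6),
      n_subjects = 7, n_days = 17, saline_from_day = 11,
      saline_decay = 0.55, classifier = "lowdose"),
    stop("unknown scenario '", scenario, "'", call. = FALSE))
}

#' Generate a synthetic cohort of subject histories
#'
#' Builds a cohort for one of the named experimental scenarios, with
#' per-subject log-normal rate variability, and returns the histories
#' together with a ground-truth manifest of the generating parameters.
#' Scenarios:
#' \describe{
#'   \item{`standard_dose`}{30 ug/kg/inf acquisition: a ~10-infusion
#'     loading burst in the first ~18 min then ~8-min maintenance
#'     intervals (~20-22 infusions/session).}
#'   \item{`cre_pos_lowdose`}{1.5 ug/kg/inf acquirers, ~18-20
#'     infusions/session, well above the 11.1 mean cutoff.}
#'   \item{`cre_neg_lowdose`, `naive_lowdose`}{1.5 ug/kg/inf
#'     non-acquirers with low, slowly declining intake.}
#'   \item{`thcre`}{17-day low-dose acquisition with escalation after day
#'     10 (~15-20 rising to ~40 infusions), plus a low-responding non-
#'     transgenic control group for the control-referenced cutoff.}
#'   \item{`saline_substitution`}{10 nicotine days followed by 7 saline
#'     days with rapidly decaying intake.}
#' }
#'
#' @param scenario Scenario name (see above).
#' @param n_subjects Number of test subjects (scenario default if NULL).
#' @param n_days Number of session days (scenario default if NULL).
#' @param seed Integer seed; cohorts are byte-identical under a fixed
#'   seed.
#' @param subject_cv Coefficient of variation of the per-subject rate
#'   multiplier.
#' @return List of class `synthetic_cohort`: `histories` (named list of
#'   [subject_history()]), `controls` (for scenarios with a reference
#'   group, else NULL), `manifest` (data frame of generating parameters),
#'   `scenario`, `classifier`.
#' @export
#' @examples
#' cohort <- generate_cohort("naive_lowdose", seed = 7)
#' sapply(cohort$histories, function(h) classify_low_dose(h)$verdict)
generate_cohort <- function(scenario, n_subjects = NULL, n_days = NULL,
                            seed = 1, subject_cv = 0.12) {
  sp <- scenario_defaults(scenario)
  if (is.null(n_subjects)) n_subjects <- sp$n_subjects
  if (is.null(n_days)) n_days <- sp$n_days
  set.seed(seed)
  sig <- sqrt(log(1 + subject_cv^2))

  gen_history <- function(cfg, sid, grp, scale, escalate = TRUE) {
    logs <- vector("list", n_days)
    phases <- character(n_days)
    for (d in seq_len(n_days)) {
      day_cfg <- cfg
      day_scale <- scale
      phase <- "acquisition"
      if (escalate && !is.null(sp$escalation_day) && d > sp$escalation_day)
        day_scale <- day_scale * sp$escalation_rate^(d - sp$escalation_day)
      if (!is.null(sp$saline_from_day) && d >= sp$saline_from_day) {
        day_scale <- day_scale * sp$saline_decay^(d - sp$saline_from_day + 1)
        day_cfg$dose_ug_per_kg <- 0
        phase <- "saline"
      }
      logs[[d]] <- generate_session(day_cfg, day = d, subject_id = sid,
                                    rate_scale = day_scale, group = grp)
      phases[d] <- phase
    }
    subject_history(logs, group = grp, phases = phases)
  }

  subjects <- sprintf("%s_%02d", scenario, seq_len(n_subjects))
  scales <- exp(stats::rnorm(n_subjects, -sig^2 / 2, sig))
  histories <- stats::setNames(vector("list", n_subjects), subjects)
  for (i in seq_len(n_subjects))
    histories[[i]] <- gen_history(sp$config, subjects[i], sp$config$group,
                                  scales[i])

  controls <- NULL
  ctrl_manifest <- NULL
  if (!is.null(sp$control_config)) {
    ctrl_ids <- sprintf("%s_ctrl_%02d", scenario, seq_len(sp$n_controls))
    ctrl_scales <- exp(stats::rnorm(sp$n_controls, -sig^2 / 2, sig))
    controls <- stats::setNames(vector("list", sp$n_controls), ctrl_ids)
    for (i in seq_len(sp$n_controls))
      controls[[i]] <- gen_history(sp$control_config, ctrl_ids[i],
                                   sp$control_config$group, ctrl_scales[i],
                                   escalate = FALSE)
    ctrl_manifest <- data.frame(subject = ctrl_ids,
                                group = sp$control_config$group,
                                rate_scale = ctrl_scales)
  }

  manifest <- rbind(
    data.frame(subject = subjects,
               group = rep(sp$config$group, n_subjects),
               rate_scale = scales),
    ctrl_manifest)
  n_man <- nrow(manifest)
  manifest$scenario <- rep(scenario, n_man)
  manifest$seed <- rep(seed, n_man)
  manifest$n_days <- rep(n_days, n_man)

  structure(list(histories = histories, controls = controls,
                 manifest = manifest, scenario = scenario,
                 classifier = sp$classifier),
            class = "synthetic_cohort")
}

#' Generate noisy Hill-shaped dose-response replicates
#'
#' Replicate responses are the Hill model value plus Gaussian noise,
#' truncated at zero. The default design follows the activation assay
#' convention: ~3-fold concentration steps spanning several orders of
#' magnitude (12 doses).
#'
#' @param ec50 True midpoint, molar.
#' @param n_hill True Hill coefficient.
#' @param top True top asymptote.
#' @param doses Molar doses (default: 12 doses, 3-fold spacing centred
#'   near `ec50`).
#' @param reps Number of replicates.
#' @param noise_sd Gaussian noise SD on the normalized response scale.
#' @param seed Optional integer seed.
#' @param direction `"activation"` or `"inhibition"`.
#' @return A [dose_response_series()] with the generating parameters
#'   attached as attribute `truth`.
#' @export
generate_dose_response <- function(ec50, n_hill = 1.5, top = 1,
                                   doses = NULL, reps = 3, noise_sd = 0.05,
                                   seed = NULL,
                                   direction = "activation") {
  if (ec50 <= 0 || n_hill <= 0 || top <= 0 || noise_sd < 0)
    stop("generating parameters must be positive (noise_sd >= 0)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(doses)) doses <- ec50 * 3^seq(-6, 5)
  conc <- rep(doses, times = reps)
  repl <- rep(seq_len(reps), each = length(doses))
  mu <- hill_value(conc, ec50, n_hill, top = top, direction = direction)
  resp <- pmax(mu + stats::rnorm(length(conc), 0, noise_sd), 0)
  out <- dose_response_series(conc, resp, repl)
  attr(out, "truth") <- list(ec50 = ec50, n_hill = n_hill, top = top,
                             direction = direction, noise_sd = noise_sd)
  out
}

# saturating coupling between stimulation intensity and per-pulse release
.intensity_gain <- function(v, v50 = 3, h = 2.5) {
  v^h / (v^h + v50^h)
}

#' Generate a synthetic voltammetry dataset
#'
#' Per-slice kinetic parameters are log-normally jittered around the group
#' means, and each slice gets (a) a standard single-pulse trace, (b) a
#' single-pulse intensity series over the standard 0.5-10 V inputs with
#' per-pulse release a saturating function of intensity, and (c) four-pulse
#' trains at 3, 10, 30 and 100 Hz. Gaussian noise is added to every sample
#' (so noisy traces can dip slightly below zero at baseline).
#'
#' @param vmax Group mean maximal uptake rate, uM/s.
#' @param da_per_pulse Group mean release per pulse, uM.
#' @param km Uptake affinity, uM (fixed, not jittered).
#' @param n_slices Number of slices.
#' @param noise_sd Additive Gaussian noise SD, uM.
#' @param jitter_cv Coefficient of variation of per-slice parameters.
#' @param seed Optional integer seed.
#' @param duration Trace duration, s.
#' @param dt Sampling interval, s (must resolve 100-Hz trains).
#' @param intensities Intensity series, V.
#' @param frequencies Train frequencies, Hz.
#' @return List of class `fscv_dataset`: `slices` (each with `single`,
#'   `intensity` (traces + intensities), `trains` (traces + frequencies))
#'   and `manifest` (true per-slice parameters).
#' @export
generate_fscv_dataset <- function(vmax = 2, da_per_pulse = 1.2, km = 0.16,
                                  n_slices = 5, noise_sd = 0.02,
                                  jitter_cv = 0.15, seed = NULL,
                                  duration = 4, dt = 0.005,
                                  intensities = c(0.5, 1, 1.5, 2, 2.5, 3,
                                                  3.5, 4, 4.5, 5, 6, 7, 8,
                                                  9, 10),
                                  frequencies = c(3, 10, 30, 100)) {
  if (!is.null(seed)) set.seed(seed)
  sig <- sqrt(log(1 + jitter_cv^2))
  noisy <- function(tr) {
    if (noise_sd > 0)
      tr$da_um <- tr$da_um + stats::rnorm(nrow(tr), 0, noise_sd)
    tr
  }
  slices <- vector("list", n_slices)
  man <- vector("list", n_slices)
  ref_gain <- .intensity_gain(7.5)
  for (s in seq_len(n_slices)) {
    vmax_s <- vmax * exp(stats::rnorm(1, -sig^2 / 2, sig))
    dap_s <- da_per_pulse * exp(stats::rnorm(1, -sig^2 / 2, sig))
    p <- mm_params(vmax = vmax_s, km = km, da_per_pulse = dap_s)
    single <- noisy(simulate_trace(p, stim_pattern(), duration, dt))
    int_traces <- lapply(intensities, function(v) {
      pv <- mm_params(vmax = vmax_s, km = km,
                      da_per_pulse = dap_s * .intensity_gain(v) / ref_gain)
      noisy(simulate_trace(pv, stim_pattern(intensity_v = v), duration, dt))
    })
    train_traces <- lapply(frequencies, function(f) {
      noisy(simulate_trace(p, stim_pattern(n_pulses = 4, frequency = f),
                           duration, dt))
    })
    slices[[s]] <- list(single = single,
                        intensity = list(traces = int_traces,
                                         intensities = intensities),
                        trains = list(traces = train_traces,
                                      frequencies = frequencies),
                        params = p)
    man[[s]] <- data.frame(slice = s, vmax = vmax_s, da_per_pulse = dap_s,
                           km = km)
  }
  structure(list(slices = slices, manifest = do.call(rbind, man)),
            class = "fscv_dataset")
}
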