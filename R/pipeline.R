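# End-to-end driver: synthetic cohort -> acquisition classifiers ->
# per-subject predicted nicotine profiles -> group mean +/- SEM band.

#' Pipeline run configuration
#'
#' Everything needed to reproduce a run: scenario, seed, PK parameter set,
#' classifier criteria and output options. A run is fully re-derivable from
#' its configuration.
#'
#' @param scenario Cohort scenario name (see [generate_cohort()]).
#' @param n_subjects,n_days Cohort size overrides (scenario defaults if
#'   NULL).
#' @param seed Integer seed.
#' @param params [pk_parameters()] used for the PK stage.
#' @param criteria [acquisition_criteria()] used for classification.
#' @param pk_day Session day whose infusion record is simulated (defaults
#'   to the last day of the classifier's evaluation window).
#' @param grid_resolution PK output grid spacing, seconds.
#' @param out_dir Optional directory for CSV outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = "standard_dose", n_subjects = NULL,
                       n_days = NULL, seed = 1,
                       params = pk_parameters(),
                       criteria = acquisition_criteria(), pk_day = NULL,
                       grid_resolution = 5, out_dir = NULL) {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(criteria, "acquisition_criteria"))
  structure(list(scenario = scenario, n_subjects = n_subjects,
                 n_days = n_days, seed = seed, params = params,
                 criteria = criteria, pk_day = pk_day,
                 grid_resolution = grid_resolution, out_dir = out_dir),
            class = "run_config")
}

classify_history <- function(history, classifier, criteria, cutoff = NULL) {
  switch(classifier,
         standard = classify_standard_dose(history, criteria),
         lowdose = classify_low_dose(history, criteria),
         control_referenced = classify_control_referenced(
           history, cutoff, criteria$control_window),
         stop("unknown classifier '", classifier, "'", call. = FALSE))
}

#' Run the cohort -> classifier -> pharmacokinetics pipeline
#'
#' Generates (or accepts) a synthetic cohort, applies the scenario's
#' acquisition classifier to every subject, simulates each subject's
#' predicted nicotine profile from one session's infusion record, and
#' summarises the profiles as a group mean +/- SEM band. With `out_dir`
#' set, writes `classification.csv`, `band.csv`, `profiles.csv` and
#' `manifest.csv`; reruns with the same configuration produce identical
#' files.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built `synthetic_cohort` (generated from the
#'   config when NULL).
#' @return List of class `pipeline_report`: `classification` (data frame),
#'   `profiles` (named list of `concentration_profile`), `band`
#'   (from [group_band()]), `metrics` (per-subject exposure metrics),
#'   `cohort`, `config`.
#' @export
#' @examples
#' rep <- run_pipeline(run_config("naive_lowdose", n_subjects = 3,
#'                                grid_resolution = 30))
#' rep$classification
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort))
    cohort <- generate_cohort(config$scenario, config$n_subjects,
                              config$n_days, seed = config$seed)
  histories <- cohort$histories
  if (!length(histories)) {
    report <- structure(list(classification = data.frame(),
                             profiles = list(), band = NULL,
                             metrics = list(), cohort = cohort,
                             config = config),
                        class = "pipeline_report")
    return(report)
  }
  criteria <- config$criteria
  cutoff <- NULL
  if (cohort$classifier == "control_referenced") {
    if (is.null(cohort$controls))
      stop("stage classify: scenario requires control histories",
           call. = FALSE)
    cutoff <- control_referenced_cutoff(cohort$controls,
                                        criteria$control_window,
                                        criteria$control_sd_multiplier)
  }
  rows <- vector("list", length(histories))
  profiles <- list()
  metrics <- list()
  window_days <- switch(cohort$classifier,
                        standard = criteria$acquisition_sessions,
                        lowdose = criteria$lowdose_window,
                        control_referenced = criteria$control_window)
  pk_day <- if (is.null(config$pk_day)) max(window_days) else config$pk_day
  for (i in seq_along(histories)) {
    h <- histories[[i]]
    out <- tryCatch(
      classify_history(h, cohort$classifier, criteria, cutoff),
      error = function(e)
        stop("stage classify, subject ", h$subject_id, ": ",
             conditionMessage(e), call. = FALSE))
    day_idx <- match(pk_day, h$days)
    if (is.na(day_idx))
      stop("stage pk, subject ", h$subject_id, ": no session on day ",
           pk_day, call. = FALSE)
    log <- h$logs[[day_idx]]
    sched <- infusion_schedule(
      infusion_times(log),
      dose_ug = max(log$dose_ug_per_kg, 1e-12) * config$params$body_mass)
    prof <- tryCatch(
      simulate_profile(sched, config$params,
                       grid_resolution = config$grid_resolution,
                       t_end = log$session_min, keep_event_times = FALSE),
      error = function(e)
        stop("stage pk, subject ", h$subject_id, ": ",
             conditionMessage(e), call. = FALSE))
    # common banding grid: the session window only (the simulated grid
    # runs past the last infusion, which differs between subjects)
    keep_rows <- prof$time_min <= log$session_min + 1e-9
    prof <- structure(prof[keep_rows, , drop = FALSE],
                      class = class(prof))
    met <- exposure_metrics(prof, c(0, log$session_min))
    rows[[i]] <- data.frame(subject = h$subject_id, group = h$group,
                            verdict = out$verdict,
                            triggered_rule = out$triggered_rule,
                            pk_day = pk_day,
                            infusions_pk_day = length(infusion_times(log)),
                            peak_ng_ml = met$peak_conc,
                            mean_ng_ml = met$mean_conc,
                            auc_ng_min_ml = met$auc)
    profiles[[h$subject_id]] <- prof
    metrics[[h$subject_id]] <- met
  }
  classification <- do.call(rbind, rows)
  band <- group_band(profiles)
  report <- structure(list(classification = classification,
                           profiles = profiles, band = band,
                           metrics = metrics, cohort = cohort,
                           config = config),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  n <- nrow(x$classification)
  cat(sprintf("Pipeline report: scenario '%s', %d subject(s)\n",
              x$config$scenario, if (is.null(n)) 0L else n))
  if (!is.null(n) && n)
    print(table(x$classification$verdict))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$classification,
                   file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cohort$manifest,
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(report$band))
    utils::write.csv(report$band, file.path(out_dir, "band.csv"),
                     row.names = FALSE)
  if (length(report$profiles)) {
    long <- do.call(rbind, lapply(names(report$profiles), function(id) {
      p <- report$profiles[[id]]
      data.frame(subject = id, time_min = p$time_min,
                 conc_ng_ml = p$conc_ng_ml)
    }))
    utils::write.csv(long, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Pointwise group mean +/- SEM concentration band
#'
#' Averages per-subject predicted concentration profiles on a common time
#' grid. The SEM is the sample SD across subjects divided by sqrt(n); with
#' a single subject it is flagged undefined (NA). Profiles on mismatched
#' grids are resampled onto the first profile's grid with a warning.
#'
#' @param profiles Named list of `concentration_profile` objects.
#' @return Data frame: `time_min`, `mean_ng_ml`, `sem_ng_ml`, `n`.
#' @export
#' @examples
#' p <- pk_parameters()
#' profs <- lapply(c(10.5, 21), function(d)
#'   simulate_profile(infusion_schedule(0, dose_ug = d), p,
#'                    grid_resolution = 30))
#' head(group_band(profs))
group_band <- function(profiles) {
  if (!length(profiles)) stop("no profiles to band", call. = FALSE)
  ref_t <- profiles[[1]]$time_min
  mat <- vapply(profiles, function(p) {
    if (length(p$time_min) != length(ref_t) ||
        max(abs(p$time_min - ref_t)) > 1e-9) {
      warning("profiles on mismatched grids; resampling to the first grid")
      stats::approx(p$time_min, p$conc_ng_ml, xout = ref_t, rule = 2)$y
    } else p$conc_ng_ml
  }, numeric(length(ref_t)))
  mat <- matrix(mat, nrow = length(ref_t))
  n <- ncol(mat)
  mean_c <- rowMeans(mat)
  sem <- if (n > 1) apply(mat, 1, stats::sd) / sqrt(n)
         else rep(NA_real_, length(ref_t))
  data.frame(time_min = ref_t, mean_ng_ml = mean_c, sem_ng_ml = sem, n = n)
}
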