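# Self-administration session logs: a minimal CSV dialect, fixed-ratio /
# timeout schedule semantics, per-session summaries and subject histories.

SESSION_HEADER <- c("subject", "group", "day", "dose_ug_per_kg", "fr",
                    "timeout_s", "session_min")
EVENT_KINDS <- c("active", "inactive", "infusion")

#' Operant session log
#'
#' One 2-h (by default) self-administration session: timestamped active
#' nose pokes, inactive nose pokes and infusions under a fixed-ratio
#' schedule with a post-infusion timeout, during which responding is
#' recorded but has no consequence. Events are kept in time order; ties are
#' kept in input order so that the poke that triggers an infusion precedes
#' it.
#'
#' @param subject_id Subject identifier.
#' @param day Session day index, integer >= 1.
#' @param events Data frame with columns `t_sec` (seconds from session
#'   start) and `kind` (one of `"active"`, `"inactive"`, `"infusion"`).
#' @param dose_ug_per_kg Nominal unit dose, ug/kg (0 for saline).
#' @param fr Fixed-ratio requirement, integer >= 1.
#' @param timeout_s Post-infusion timeout, seconds.
#' @param session_min Session length, minutes.
#' @param group Optional group label.
#' @return An object of class `session_log`.
#' @export
#' @examples
#' ev <- data.frame(t_sec = c(10, 10, 35, 35),
#'                  kind = c("active", "infusion", "active", "infusion"))
#' log <- session_log("r1", 1, ev, dose_ug_per_kg = 30)
#' session_summary(log)
session_log <- function(subject_id, day,
                        events = data.frame(t_sec = numeric(0),
                                            kind = character(0)),
                        dose_ug_per_kg = 30, fr = 1, timeout_s = 20,
                        session_min = 120, group = NA_character_) {
  if (day < 1 || day != round(day))
    stop("session_log: 'day' must be a positive integer", call. = FALSE)
  if (fr < 1 || fr != round(fr))
    stop("session_log: 'fr' must be a positive integer", call. = FALSE)
  if (timeout_s < 0 || session_min <= 0 || dose_ug_per_kg < 0)
    stop("session_log: invalid schedule parameters", call. = FALSE)
  if (!all(c("t_sec", "kind") %in% names(events)))
    stop("session_log: events need 't_sec' and 'kind' columns",
         call. = FALSE)
  events$kind <- as.character(events$kind)
  bad_kind <- !events$kind %in% EVENT_KINDS
  if (any(bad_kind))
    stop("session_log: unknown event kind '", events$kind[bad_kind][1], "'",
         call. = FALSE)
  if (any(events$t_sec < 0 | events$t_sec > session_min * 60))
    stop("session_log: event timestamp outside [0, session length]",
         call. = FALSE)
  # stable sort: ties keep input order (poke before the infusion it earns)
  events <- events[order(events$t_sec), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(subject_id = as.character(subject_id), day = as.integer(day),
                 events = events, dose_ug_per_kg = dose_ug_per_kg,
                 fr = as.integer(fr), timeout_s = timeout_s,
                 session_min = session_min, group = as.character(group)),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  s <- session_summary(x)
  cat(sprintf("Session log: subject %s, day %d (%g min, FR%d/TO-%gs, %g ug/kg)\n",
              x$subject_id, x$day, x$session_min, x$fr, x$timeout_s,
              x$dose_ug_per_kg))
  cat(sprintf("  %d infusions, %d active, %d inactive pokes\n",
              s$infusions, s$active, s$inactive))
  invisible(x)
}

#' Write a session log in the package CSV dialect
#'
#' The dialect is two CSV blocks in one file: a one-row header block with
#' columns `subject, group, day, dose_ug_per_kg, fr, timeout_s, session_min`
#' followed by an event block with columns `t_sec, kind`.
#'
#' @param log A [session_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  lines <- c(paste(SESSION_HEADER, collapse = ","),
             paste(log$subject_id, log$group, log$day, log$dose_ug_per_kg,
                   log$fr, log$timeout_s, log$session_min, sep = ","),
             "t_sec,kind")
  if (nrow(log$events))
    lines <- c(lines, paste(vapply(log$events$t_sec, format, character(1),
                                   digits = 17, scientific = FALSE),
                            log$events$kind, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a session log from the package CSV dialect
#'
#' Counterpart of [write_session_log()]. Malformed rows are reported with
#' their line numbers.
#'
#' @param path Path to a session-log file.
#' @return A validated [session_log()].
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("parse error: file too short for the session-log dialect",
         call. = FALSE)
  if (trimws(lines[1]) != paste(SESSION_HEADER, collapse = ","))
    stop("parse error at line 1: expected header '",
         paste(SESSION_HEADER, collapse = ","), "'", call. = FALSE)
  if (any(trimws(lines[-1]) == paste(SESSION_HEADER, collapse = ",")))
    stop("parse error: duplicate header block", call. = FALSE)
  hdr <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (length(hdr) != length(SESSION_HEADER))
    stop("parse error at line 2: expected ", length(SESSION_HEADER),
         " header fields", call. = FALSE)
  if (trimws(lines[3]) != "t_sec,kind")
    stop("parse error at line 3: expected event header 't_sec,kind'",
         call. = FALSE)
  ev_lines <- lines[-(1:3)]
  ev_lines_idx <- seq_along(ev_lines) + 3L
  keep <- nzchar(trimws(ev_lines))
  ev_lines <- ev_lines[keep]
  ev_lines_idx <- ev_lines_idx[keep]
  t_sec <- numeric(length(ev_lines))
  kind <- character(length(ev_lines))
  for (i in seq_along(ev_lines)) {
    parts <- trimws(strsplit(ev_lines[i], ",", fixed = TRUE)[[1]])
    if (length(parts) != 2L)
      stop("parse error at line ", ev_lines_idx[i],
           ": expected 't_sec,kind'", call. = FALSE)
    tv <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(tv))
      stop("parse error at line ", ev_lines_idx[i],
           ": non-numeric timestamp '", parts[1], "'", call. = FALSE)
    if (!parts[2] %in% EVENT_KINDS)
      stop("parse error at line ", ev_lines_idx[i],
           ": unknown event kind '", parts[2], "'", call. = FALSE)
    t_sec[i] <- tv
    kind[i] <- parts[2]
  }
  session_min <- as.numeric(hdr[7])
  if (any(t_sec < 0 | t_sec > session_min * 60)) {
    bad <- which(t_sec < 0 | t_sec > session_min * 60)[1]
    stop("parse error at line ", ev_lines_idx[bad],
         ": timestamp outside [0, session length]", call. = FALSE)
  }
  session_log(subject_id = hdr[1], day = as.integer(hdr[3]),
              events = data.frame(t_sec = t_sec, kind = kind),
              dose_ug_per_kg = as.numeric(hdr[4]), fr = as.integer(hdr[5]),
              timeout_s = as.numeric(hdr[6]), session_min = session_min,
              group = hdr[2])
}

#' Check fixed-ratio / timeout schedule semantics
#'
#' Replays a session log against the schedule: an infusion is legitimate
#' only if (a) the post-infusion timeout of the previous infusion has
#' expired and (b) exactly `fr` active pokes outside timeout have occurred
#' since the previous infusion. Active pokes during the timeout are
#' recorded but never count toward the next ratio.
#'
#' @param log A [session_log()].
#' @return A data frame of violations (`t_sec`, `message`); zero rows when
#'   the log is consistent with the schedule.
#' @export
#' @examples
#' ev <- data.frame(t_sec = c(10, 10, 15, 35, 35),
#'                  kind = c("active", "infusion", "active",
#'                           "active", "infusion"))
#' validate_schedule_semantics(session_log("r1", 1, ev))  # no violations
validate_schedule_semantics <- function(log) {
  stopifnot(inherits(log, "session_log"))
  ev <- log$events
  counted <- 0L
  last_inf <- -Inf
  viol_t <- numeric(0)
  viol_msg <- character(0)
  for (i in seq_len(nrow(ev))) {
    t <- ev$t_sec[i]
    kind <- ev$kind[i]
    if (kind == "active") {
      if (t >= last_inf + log$timeout_s) counted <- counted + 1L
    } else if (kind == "infusion") {
      if (t < last_inf + log$timeout_s) {
        viol_t <- c(viol_t, t)
        viol_msg <- c(viol_msg, sprintf(
          "infusion at %g s within the %g-s timeout of the infusion at %g s",
          t, log$timeout_s, last_inf))
      } else if (counted != log$fr) {
        viol_t <- c(viol_t, t)
        viol_msg <- c(viol_msg, sprintf(
          "infusion at %g s after %d counted active pokes (FR is %d)",
          t, counted, log$fr))
      }
      last_inf <- t
      counted <- 0L
    }
  }
  data.frame(t_sec = viol_t, message = viol_msg,
             stringsAsFactors = FALSE)
}

#' Per-session response summary
#'
#' Counts of infusions and active/inactive pokes plus the
#' active-to-inactive ratio. The ratio is `Inf` when there are active pokes
#' but no inactive pokes (the animal discriminates perfectly) and flagged
#' undefined when there are no pokes at all; an undefined ratio is treated
#' as failing any ratio criterion.
#'
#' @param log A [session_log()].
#' @return One-row data frame: `infusions`, `active`, `inactive`, `ratio`,
#'   `ratio_defined`.
#' @export
session_summary <- function(log) {
  stopifnot(inherits(log, "session_log"))
  k <- log$events$kind
  active <- sum(k == "active")
  inactive <- sum(k == "inactive")
  ratio_defined <- active > 0 || inactive > 0
  ratio <- if (!ratio_defined) NA_real_
           else if (inactive == 0) Inf
           else active / inactive
  data.frame(infusions = sum(k == "infusion"), active = active,
             inactive = inactive, ratio = ratio,
             ratio_defined = ratio_defined)
}

#' Infusion time vector for pharmacokinetic simulation
#'
#' Sorted pump-onset timestamps of the session's infusions, converted from
#' seconds to minutes, in the form consumed by [infusion_schedule()].
#'
#' @param log A [session_log()].
#' @return Numeric vector of minutes; empty when the session has no
#'   infusions (yielding an all-zero predicted profile).
#' @export
infusion_times <- function(log) {
  stopifnot(inherits(log, "session_log"))
  sort(log$events$t_sec[log$events$kind == "infusion"]) / 60
}

#' Subject history across sessions
#'
#' Ordered collection of one subject's session logs with optional phase
#' annotations (e.g. acquisition vs saline substitution). Day indices must
#' be strictly increasing with at most one session per day.
#'
#' @param logs List of [session_log()] objects for a single subject.
#' @param group Optional group label (defaults to the first log's).
#' @param phases Optional character vector, one phase label per session.
#' @return An object of class `subject_history`.
#' @export
subject_history <- function(logs, group = NULL, phases = NULL) {
  if (!length(logs) || !all(vapply(logs, inherits, logical(1), "session_log")))
    stop("subject_history: 'logs' must be a non-empty list of session logs",
         call. = FALSE)
  ids <- unique(vapply(logs, `[[`, character(1), "subject_id"))
  if (length(ids) != 1L)
    stop("subject_history: logs from more than one subject", call. = FALSE)
  days <- vapply(logs, `[[`, integer(1), "day")
  o <- order(days)
  logs <- logs[o]
  days <- days[o]
  if (anyDuplicated(days))
    stop("subject_history: more than one session on day ",
         days[duplicated(days)][1], call. = FALSE)
  if (!is.null(phases)) {
    if (length(phases) != length(logs))
      stop("subject_history: one phase label per session required",
           call. = FALSE)
    phases <- phases[o]
  }
  if (is.null(group)) group <- logs[[1]]$group
  structure(list(subject_id = ids, group = as.character(group),
                 logs = logs, days = days, phases = phases),
            class = "subject_history")
}

#' @export
print.subject_history <- function(x, ...) {
  cat(sprintf("Subject %s (%s): %d sessions, days %d-%d\n", x$subject_id,
              x$group, length(x$logs), min(x$days), max(x$days)))
  invisible(x)
}

# summary table across a history, one row per session (day order)
history_table <- function(history) {
  stopifnot(inherits(history, "subject_history"))
  tab <- do.call(rbind, lapply(history$logs, session_summary))
  tab$day <- history$days
  tab
}

#' Mean infusions per session over a window of days
#'
#' Arithmetic mean of per-session infusion counts over `days`; every day in
#' the range must be present in the history.
#'
#' @param history A [subject_history()].
#' @param days Integer vector of day indices, e.g. `6:10`.
#' @return Mean infusions per session.
#' @export
phase_mean_infusions <- function(history, days) {
  stopifnot(inherits(history, "subject_history"))
  missing_days <- setdiff(days, history$days)
  if (length(missing_days))
    stop("history does not cover day(s) ",
         paste(missing_days, collapse = ", "), call. = FALSE)
  tab <- history_table(history)
  mean(tab$infusions[match(days, tab$day)])
}

#' Acquisition criteria
#'
#' Thresholds of the cohort-specific acquisition-failure rules. The
#' defaults are the rule set used throughout the package: at the standard
#' training dose, failure is triggered by fewer than 10 infusions in 2 or
#' more consecutive sessions, an active:inactive ratio below 2.0 in 3 or
#' more consecutive sessions, or a drop in active responding of 75% or more
#' (relative to the mean of sessions 1-5) during sessions 6-10. At the low
#' unit dose, failure is a mean below 11.1 infusions across days 6-10
#' (the saline self-administration reference level). For the
#' control-referenced rule, the cutoff is the control-group mean across
#' days 11-17 plus 2 standard deviations.
#'
#' @param min_infusions Rule-1 infusion threshold (strictly below fails).
#' @param consecutive_infusion_sessions Rule-1 run length.
#' @param min_ratio Rule-2 active:inactive threshold (strictly below fails).
#' @param consecutive_ratio_sessions Rule-2 run length.
#' @param drop_fraction Rule-3 fractional drop (inclusive).
#' @param drop_window Sessions in which rule 3 is evaluated.
#' @param baseline_window Sessions defining the rule-3 baseline.
#' @param acquisition_sessions Sessions over which rules 1-2 are evaluated.
#' @param lowdose_mean_cutoff Low-dose mean-infusion cutoff.
#' @param lowdose_window Day window for the low-dose rule.
#' @param control_sd_multiplier SD multiplier for the control-referenced
#'   cutoff.
#' @param control_window Day window for the control-referenced rule.
#' @return A list of class `acquisition_criteria`.
#' @export
acquisition_criteria <- function(min_infusions = 10,
                                 consecutive_infusion_sessions = 2,
                                 min_ratio = 2.0,
                                 consecutive_ratio_sessions = 3,
                                 drop_fraction = 0.75,
                                 drop_window = 6:10,
                                 baseline_window = 1:5,
                                 acquisition_sessions = 1:10,
                                 lowdose_mean_cutoff = 11.1,
                                 lowdose_window = 6:10,
                                 control_sd_multiplier = 2,
                                 control_window = 11:17) {
  if (min_infusions <= 0 || min_ratio <= 0 || drop_fraction <= 0 ||
      drop_fraction > 1 || lowdose_mean_cutoff <= 0 ||
      control_sd_multiplier <= 0)
    stop("acquisition_criteria: thresholds must be positive (and the drop ",
         "fraction at most 1)", call. = FALSE)
  structure(list(min_infusions = min_infusions,
                 consecutive_infusion_sessions = consecutive_infusion_sessions,
                 min_ratio = min_ratio,
                 consecutive_ratio_sessions = consecutive_ratio_sessions,
                 drop_fraction = drop_fraction, drop_window = drop_window,
                 baseline_window = baseline_window,
                 acquisition_sessions = acquisition_sessions,
                 lowdose_mean_cutoff = lowdose_mean_cutoff,
                 lowdose_window = lowdose_window,
                 control_sd_multiplier = control_sd_multiplier,
                 control_window = control_window),
            class = "acquisition_criteria")
}

acquisition_outcome <- function(verdict, triggered_rule = NA_character_,
                                details = list()) {
  structure(list(verdict = verdict, triggered_rule = triggered_rule,
                 details = details),
            class = "acquisition_outcome")
}

#' @export
print.acquisition_outcome <- function(x, ...) {
  cat("Acquisition verdict:", x$verdict)
  if (!is.na(x$triggered_rule)) cat(" (", x$triggered_rule, ")", sep = "")
  cat("\n")
  invisible(x)
}

# longest run of TRUE in a logical vector
.max_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Classify acquisition at the standard training dose
#'
#' Applies the three standard-dose failure rules over the acquisition
#' sessions (in session order): (1) infusions strictly below the threshold
#' in two or more consecutive sessions; (2) active:inactive ratio strictly
#' below 2.0 (an undefined ratio from a non-responding session also counts)
#' in three or more consecutive sessions; (3) active responding in any of
#' sessions 6-10 dropping by 75% or more (inclusive) from the mean of
#' sessions 1-5. The first triggered rule is recorded.
#'
#' @param history A [subject_history()] with at least 10 acquisition
#'   sessions.
#' @param criteria An [acquisition_criteria()] object.
#' @return An `acquisition_outcome`: `verdict` (`"acquired"`/`"failed"`),
#'   `triggered_rule` and the per-session supporting values.
#' @export
classify_standard_dose <- function(history,
                                   criteria = acquisition_criteria()) {
  stopifnot(inherits(history, "subject_history"),
            inherits(criteria, "acquisition_criteria"))
  tab <- history_table(history)
  idx <- criteria$acquisition_sessions
  if (nrow(tab) < max(idx))
    stop("history has ", nrow(tab), " sessions; ", max(idx),
         " acquisition sessions required", call. = FALSE)
  tab <- tab[seq_len(max(idx)), , drop = FALSE]

  low_inf <- tab$infusions < criteria$min_infusions
  rule1 <- .max_run(low_inf) >= criteria$consecutive_infusion_sessions

  low_ratio <- ifelse(tab$ratio_defined, tab$ratio < criteria$min_ratio, TRUE)
  rule2 <- .max_run(low_ratio) >= criteria$consecutive_ratio_sessions

  baseline <- mean(tab$active[criteria$baseline_window])
  drop_active <- tab$active[criteria$drop_window]
  rule3 <- baseline > 0 &&
    any(drop_active <= (1 - criteria$drop_fraction) * baseline)

  details <- list(infusions = tab$infusions, ratios = tab$ratio,
                  active = tab$active, baseline_active = baseline)
  if (rule1) acquisition_outcome("failed", "low_infusions", details)
  else if (rule2) acquisition_outcome("failed", "low_ratio", details)
  else if (rule3) acquisition_outcome("failed", "response_drop", details)
  else acquisition_outcome("acquired", details = details)
}

#' Classify acquisition at the low unit dose
#'
#' A subject fails when its mean infusions across the low-dose window
#' (days 6-10) is strictly below the saline-reference cutoff of 11.1
#' infusions; a mean exactly at the cutoff maintains it and acquires.
#'
#' @inheritParams classify_standard_dose
#' @return An `acquisition_outcome` with the window mean in `details`.
#' @export
classify_low_dose <- function(history, criteria = acquisition_criteria()) {
  stopifnot(inherits(history, "subject_history"),
            inherits(criteria, "acquisition_criteria"))
  m <- phase_mean_infusions(history, criteria$lowdose_window)
  details <- list(window_mean = m, cutoff = criteria$lowdose_mean_cutoff)
  if (m < criteria$lowdose_mean_cutoff)
    acquisition_outcome("failed", "below_mean_cutoff", details)
  else acquisition_outcome("acquired", details = details)
}

#' Control-referenced acquisition cutoff
#'
#' Cutoff for the transgenic cohort: the mean of per-control-subject window
#' means of infusions (days 11-17 by default) plus `sd_multiplier` sample
#' standard deviations of those means.
#'
#' @param control_histories List of control [subject_history()] objects
#'   (at least 2, each covering the window).
#' @param days Day window, e.g. `11:17`.
#' @param sd_multiplier Number of SDs above the control mean.
#' @return The cutoff in infusions per session, with the per-subject means
#'   attached as attribute `control_means`.
#' @export
control_referenced_cutoff <- function(control_histories, days = 11:17,
                                      sd_multiplier = 2) {
  if (length(control_histories) < 2L)
    stop("at least 2 control subjects are required for an SD-based cutoff",
         call. = FALSE)
  means <- vapply(control_histories, phase_mean_infusions, numeric(1),
                  days = days)
  cutoff <- mean(means) + sd_multiplier * stats::sd(means)
  attr(cutoff, "control_means") <- means
  cutoff
}

#' Classify acquisition against a control-referenced cutoff
#'
#' A test subject fails when its mean infusions across the window is
#' strictly below the cutoff from [control_referenced_cutoff()].
#'
#' @param history A [subject_history()].
#' @param cutoff Cutoff in infusions per session.
#' @param days Day window matching the cutoff.
#' @return An `acquisition_outcome`.
#' @export
classify_control_referenced <- function(history, cutoff, days = 11:17) {
  m <- phase_mean_infusions(history, days)
  details <- list(window_mean = m, cutoff = as.numeric(cutoff))
  if (m < cutoff)
    acquisition_outcome("failed", "below_control_cutoff", details)
  else acquisition_outcome("acquired", details = details)
}

#' Paired change in window means (e.g. saline substitution)
#'
#' Per-subject difference between the mean infusions of a post window and a
#' pre window (post minus pre); negative values indicate extinction of
#' responding after e.g. a switch to saline.
#'
#' @param history A [subject_history()] covering both windows.
#' @param pre_days,post_days Day windows.
#' @return Named list: `pre_mean`, `post_mean`, `difference`.
#' @export
substitution_effect <- function(history, pre_days, post_days) {
  pre <- phase_mean_infusions(history, pre_days)
  post <- phase_mean_infusions(history, post_days)
  list(pre_mean = pre, post_mean = post, difference = post - pre)
}
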