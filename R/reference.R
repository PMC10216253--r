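# Canonical reconstructed session schedules for the predicted-CSF
# steady-state analyses.

#' Reconstructed self-administration infusion schedules
#'
#' Stylised 2-h infusion records capturing the two characteristic intake
#' patterns seen during acquisition, used for the package's predicted-CSF
#' nicotine analyses:
#' \describe{
#'   \item{`"standard"`}{loading-then-maintenance at the standard training
#'     dose (30 ug/kg/inf): 10 loading infusions evenly spaced over minutes
#'     0-18, then 12 maintenance infusions every 8 min from minute 26 to
#'     114 (22 infusions in total).}
#'   \item{`"lowdose"`}{back-loaded intake at the low unit dose
#'     (1.5 ug/kg/inf): 10 infusions evenly spaced over minutes 0-60 and 30
#'     infusions evenly spaced over minutes 60-118 (40 in total), the
#'     less-pronounced loading / late-boosting pattern of low-dose
#'     sessions.}
#' }
#'
#' @param pattern `"standard"` or `"lowdose"`.
#' @param dose_ug_per_kg Unit dose (defaults to 30 for `"standard"`, 1.5
#'   for `"lowdose"`).
#' @param body_mass Body mass, kg.
#' @return An [infusion_schedule()].
#' @export
#' @examples
#' sched <- reference_session_schedule("standard")
#' length(sched$times_min)  # 22
reference_session_schedule <- function(pattern = c("standard", "lowdose"),
                                       dose_ug_per_kg = NULL,
                                       body_mass = 0.35) {
  pattern <- match.arg(pattern)
  if (pattern == "standard") {
    if (is.null(dose_ug_per_kg)) dose_ug_per_kg <- 30
    times <- c(seq(0, 18, length.out = 10), seq(26, 114, by = 8))
  } else {
    if (is.null(dose_ug_per_kg)) dose_ug_per_kg <- 1.5
    times <- c(seq(0, 60, length.out = 10), 60 + seq_len(30) * (58 / 30))
  }
  infusion_schedule(times, dose_ug_per_kg = dose_ug_per_kg,
                    body_mass = body_mass)
}
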