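# Shared fixtures: independent oracles and small constructors used across
# the test files. Everything is generated in code; no stored data.

# Independent explicit-Euler integration of the Michaelis-Menten uptake
# model with instantaneous per-pulse release. Deliberately naive (fixed
# small step, forward Euler) so it shares nothing with the package's
# segment-wise adaptive integrator.
euler_mm_trace <- function(vmax, km, da_per_pulse, pulse_times, duration,
                           dt = 1e-4) {
  n <- round(duration / dt)
  pulse_idx <- round(pulse_times / dt)
  y <- 0
  out <- numeric(n + 1)
  for (i in 0:n) {
    if (any(pulse_idx == i)) y <- y + da_per_pulse
    out[i + 1] <- y
    y <- y - dt * vmax * y / (km + y)
  }
  list(time = (0:n) * dt, da = out)
}

# Random infusion schedule on integer seconds (so simulation grids align
# exactly across schedules sharing a grid resolution).
random_schedule <- function(n_max = 12, t_max_s = 7200) {
  n <- sample(1:n_max, 1)
  t <- sort(sample(0:(t_max_s - 1), n))
  infusion_schedule(t / 60, dose_ug = stats::runif(n, 1, 20))
}

# Session log with prescribed event counts (classifier tests only; makes
# no attempt to satisfy FR/timeout semantics).
make_counts_session <- function(day, infusions, active, inactive,
                                subject = "S1", dose = 30,
                                session_min = 120) {
  blocks <- list()
  if (infusions > 0)
    blocks$inf <- data.frame(t_sec = seq(30, by = 45,
                                         length.out = infusions),
                             kind = "infusion")
  if (active > 0)
    blocks$act <- data.frame(t_sec = seq(10, by = 23, length.out = active),
                             kind = "active")
  if (inactive > 0)
    blocks$ina <- data.frame(t_sec = seq(17, by = 31,
                                         length.out = inactive),
                             kind = "inactive")
  ev <- if (length(blocks)) do.call(rbind, blocks)
        else data.frame(t_sec = numeric(0), kind = character(0))
  session_log(subject, day, ev, dose_ug_per_kg = dose,
              session_min = session_min)
}

# History from per-day count vectors (recycled to equal length).
make_counts_history <- function(infusions, active = NULL, inactive = NULL,
                                subject = "S1") {
  n <- length(infusions)
  if (is.null(active)) active <- pmax(infusions, 1) * 4
  if (is.null(inactive)) inactive <- rep(1, n)
  logs <- lapply(seq_len(n), function(d)
    make_counts_session(d, infusions[d], active[d], inactive[d],
                        subject = subject))
  subject_history(logs)
}
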