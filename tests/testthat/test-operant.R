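# Session-log dialect, FR/timeout semantics, summaries and the three
# cohort-specific acquisition classifiers.

test_that("session logs round-trip through the CSV dialect", {
  ev <- data.frame(t_sec = c(10, 10, 15, 35, 35, 50),
                   kind = c("active", "infusion", "active", "active",
                            "infusion", "inactive"))
  log <- session_log("r7", 3, ev, dose_ug_per_kg = 1.5, group = "crepos")
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_equal(back$subject_id, "r7")
  expect_equal(back$day, 3L)
  expect_equal(back$group, "crepos")
  expect_equal(back$dose_ug_per_kg, 1.5)
  expect_equal(back$events$t_sec, log$events$t_sec)
  expect_equal(back$events$kind, log$events$kind)

  # empty event section parses to an empty, zero-summary log
  empty <- session_log("r8", 1)
  write_session_log(empty, path)
  back2 <- read_session_log(path)
  expect_equal(nrow(back2$events), 0L)
  expect_equal(session_summary(back2)$infusions, 0)
  expect_false(session_summary(back2)$ratio_defined)
})

test_that("malformed log files raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".csv")
  good_head <- c("subject,group,day,dose_ug_per_kg,fr,timeout_s,session_min",
                 "r1,g,1,30,1,20,120", "t_sec,kind")
  writeLines(c(good_head, "10,active", "20,lever"), path)
  expect_error(read_session_log(path), "line 5.*lever")
  writeLines(c(good_head, "abc,active"), path)
  expect_error(read_session_log(path), "line 4.*non-numeric")
  writeLines(c(good_head, "9999999,active"), path)
  expect_error(read_session_log(path), "line 4.*outside")
  writeLines(c(good_head, "10,active", good_head[1]), path)
  expect_error(read_session_log(path), "duplicate header")
  writeLines(c("bad,header", "r1,g,1,30,1,20,120", "t_sec,kind"), path)
  expect_error(read_session_log(path), "line 1")
  expect_error(session_log("r1", 1, data.frame(t_sec = 1, kind = "lever")),
               "unknown event kind")
})

test_that("schedule semantics validator accepts a hand-traced FR1 session", {
  # infusion at 10 s from one poke; poke at 15 s falls inside the 20-s
  # timeout and must not count; the poke at 35 s earns the next infusion
  ev <- data.frame(t_sec = c(10, 10, 15, 35, 35),
                   kind = c("active", "infusion", "active", "active",
                            "infusion"))
  expect_identical(nrow(validate_schedule_semantics(session_log("r1", 1, ev))),
                   0L)
})

test_that("schedule semantics validator flags timeout and ratio violations", {
  # second infusion 5 s after the first: timeout not expired
  ev <- data.frame(t_sec = c(10, 10, 15, 15),
                   kind = c("active", "infusion", "active", "infusion"))
  v <- validate_schedule_semantics(session_log("r1", 1, ev))
  expect_equal(nrow(v), 1L)
  expect_match(v$message, "timeout")

  # FR5 but only 4 counted actives before the infusion
  ev5 <- data.frame(t_sec = c(10, 12, 14, 16, 18),
                    kind = c(rep("active", 4), "infusion"))
  v5 <- validate_schedule_semantics(session_log("r1", 1, ev5, fr = 5))
  expect_equal(nrow(v5), 1L)
  expect_match(v5$message, "4 counted")
})

test_that("session summaries handle the ratio edge cases", {
  s <- session_summary(make_counts_session(1, 20, 40, 10))
  expect_equal(s$ratio, 4)
  s2 <- session_summary(make_counts_session(1, 5, 12, 0))
  expect_identical(s2$ratio, Inf)
  expect_true(s2$ratio_defined)
  s3 <- session_summary(make_counts_session(1, 0, 0, 0))
  expect_true(is.na(s3$ratio))
  expect_false(s3$ratio_defined)
})

test_that("window means require full coverage and match arithmetic", {
  h <- make_counts_history(c(5, 6, 7, 8, 9, 12, 11, 10, 12, 10))
  expect_equal(phase_mean_infusions(h, 6:10), 11)
  expect_equal(phase_mean_infusions(h, 7), 11)
  h2 <- make_counts_history(c(rep(1, 5), 11, 11, 11, 12, 11))
  expect_equal(phase_mean_infusions(h2, 6:10), 11.2)
  expect_error(phase_mean_infusions(h, 6:12), "cover")
})

test_that("standard-dose rule 1 fires on runs of low-infusion sessions", {
  # sessions 6 and 7 with 9 infusions each: two consecutive below 10
  inf <- c(15, 15, 15, 15, 15, 9, 9, 15, 15, 15)
  out <- classify_standard_dose(make_counts_history(inf))
  expect_equal(out$verdict, "failed")
  expect_equal(out$triggered_rule, "low_infusions")
  # isolated single low session does not fail
  inf2 <- c(15, 15, 15, 15, 15, 9, 15, 9, 15, 15)
  expect_equal(classify_standard_dose(make_counts_history(inf2))$verdict,
               "acquired")
  # exactly 10 infusions is not "below 10"
  inf3 <- c(rep(10, 10))
  expect_equal(classify_standard_dose(make_counts_history(inf3))$verdict,
               "acquired")
})

test_that("standard-dose rule 2 uses a strict ratio inequality", {
  # ratio exactly 2.0 for all ten sessions: never a failure
  h_eq <- make_counts_history(rep(15, 10), active = rep(40, 10),
                              inactive = rep(20, 10))
  expect_equal(classify_standard_dose(h_eq)$verdict, "acquired")
  # ratio 1.95 on three consecutive sessions fails
  act <- rep(40, 10); ina <- rep(10, 10)
  ina[4:6] <- 21
  out <- classify_standard_dose(make_counts_history(rep(15, 10), act, ina))
  expect_equal(out$triggered_rule, "low_ratio")
  # two consecutive low-ratio sessions are tolerated
  ina2 <- rep(10, 10); ina2[4:5] <- 21
  expect_equal(classify_standard_dose(
    make_counts_history(rep(15, 10), act, ina2))$verdict, "acquired")
  # a non-responding session (0 active, 0 inactive) counts against the run
  act3 <- rep(40, 10); ina3 <- rep(10, 10)
  act3[4] <- 0; ina3[4] <- 0; ina3[5:6] <- 21
  expect_equal(classify_standard_dose(
    make_counts_history(rep(15, 10), act3, ina3))$triggered_rule,
    "low_ratio")
})

test_that("standard-dose rule 3 fires on a >=75% drop from the days 1-5 baseline", {
  act <- c(rep(100, 5), 100, 100, 25, 100, 100)  # exactly 75% drop, inclusive
  out <- classify_standard_dose(
    make_counts_history(rep(15, 10), act, rep(10, 10)))
  expect_equal(out$triggered_rule, "response_drop")
  act2 <- c(rep(100, 5), 100, 100, 26, 100, 100)  # 74% drop: acquired
  expect_equal(classify_standard_dose(
    make_counts_history(rep(15, 10), act2, rep(10, 10)))$verdict,
    "acquired")
  expect_error(classify_standard_dose(make_counts_history(rep(15, 5))),
               "sessions")
})

test_that("low-dose classification fails strictly below the 11.1 mean", {
  h <- make_counts_history(c(rep(12, 5), 12, 11, 11, 11, 10))
  expect_equal(phase_mean_infusions(h, 6:10), 11)
  expect_equal(classify_low_dose(h)$verdict, "failed")
  expect_equal(classify_low_dose(h)$triggered_rule, "below_mean_cutoff")
  # mean exactly at the cutoff maintains it
  crit <- acquisition_criteria(lowdose_mean_cutoff = 11)
  expect_equal(classify_low_dose(h, crit)$verdict, "acquired")
  h_hi <- make_counts_history(rep(25, 10))
  expect_equal(classify_low_dose(h_hi)$verdict, "acquired")
  h_lo <- make_counts_history(rep(5, 10))
  expect_equal(classify_low_dose(h_lo)$verdict, "failed")
})

test_that("control-referenced cutoff is mean + k * sample SD of window means", {
  mk <- function(count) make_counts_history(rep(count, 17))
  ctrl <- lapply(c(3, 3, 4, 4, 5, 5), mk)
  cut <- control_referenced_cutoff(ctrl, 11:17, 2)
  expect_equal(as.numeric(cut), 4 + 2 * sd(c(3, 3, 4, 4, 5, 5)),
               tolerance = 1e-12)
  expect_equal(as.numeric(cut), 5.7888543820, tolerance = 1e-9)
  # degenerate: identical controls give SD 0 and cutoff = mean
  cut0 <- control_referenced_cutoff(lapply(c(4, 4, 4, 4, 4, 4), mk), 11:17)
  expect_equal(as.numeric(cut0), 4)
  expect_error(control_referenced_cutoff(list(mk(4)), 11:17), "at least 2")
  # subject below the cutoff fails, at or above acquires
  expect_equal(classify_control_referenced(mk(5), 6, 11:17)$verdict,
               "failed")
  expect_equal(classify_control_referenced(mk(6), 6, 11:17)$verdict,
               "acquired")
})

test_that("substitution effects are paired window-mean differences", {
  h <- make_counts_history(c(rep(20, 10), rep(5, 7)))
  eff <- substitution_effect(h, 6:10, 11:17)
  expect_equal(eff$difference, -15)
  eff0 <- substitution_effect(h, 6:10, 6:10)
  expect_equal(eff0$difference, 0)
  h2 <- make_counts_history(c(rep(18, 10), rep(6, 7)))
  expect_equal(substitution_effect(h2, 6:10, 11:17)$difference, -12)
})

test_that("classifier verdicts are monotone in added infusions", {
  inf <- c(15, 15, 15, 15, 15, 9, 9, 15, 15, 15)
  stopifnot(classify_standard_dose(make_counts_history(inf))$verdict ==
              "failed")
  inf_more <- inf + 5
  expect_equal(classify_standard_dose(make_counts_history(inf_more))$verdict,
               "acquired")
  low <- make_counts_history(rep(8, 10))
  stopifnot(classify_low_dose(low)$verdict == "failed")
  expect_equal(classify_low_dose(make_counts_history(rep(14, 10)))$verdict,
               "acquired")
})

test_that("infusion time vectors are sorted minutes", {
  ev <- data.frame(t_sec = c(600, 60, 60, 600),
                   kind = c("active", "active", "infusion", "infusion"))
  log <- session_log("r1", 1, ev)
  expect_equal(infusion_times(log), c(1, 10))
  expect_equal(infusion_times(session_log("r1", 1)), numeric(0))
  # feeds directly into the simulator: no infusions, zero profile
  prof <- simulate_profile(
    infusion_schedule(infusion_times(session_log("r1", 1)), dose_ug = 1),
    pk_parameters(), grid_resolution = 60)
  expect_true(all(prof$conc_ng_ml == 0))
})
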