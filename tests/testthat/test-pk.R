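# Two-compartment simulator vs closed-form disposition, exposure metrics,
# and dosing-mode equivalence.

test_that("disposition eigenvalues follow the rate-matrix trace and determinant", {
  p <- pk_parameters()
  lam <- disposition_rates(p)
  expect_gt(lam[["lambda_fast"]], lam[["lambda_slow"]])
  expect_gt(lam[["lambda_slow"]], 0)
  expect_equal(sum(lam), p$k_el + p$k_cp + p$k_pc, tolerance = 1e-12)
  expect_equal(prod(lam), p$k_el * p$k_pc, tolerance = 1e-12)
  # randomised parameter sets satisfy the same identities
  set.seed(41)
  for (i in 1:20) {
    q <- pk_parameters(k_el = runif(1, 0.1, 3), k_cp = runif(1, 0.1, 3),
                       k_pc = runif(1, 0.1, 3))
    lam <- disposition_rates(q)
    expect_equal(sum(lam), q$k_el + q$k_cp + q$k_pc, tolerance = 1e-10)
    expect_equal(prod(lam), q$k_el * q$k_pc, tolerance = 1e-10)
  }
})

test_that("analytic bolus starts at dose/Vc and decays biexponentially", {
  p <- pk_parameters()
  expect_equal(analytic_bolus(10.5, p, 0), 6)
  expect_equal(analytic_bolus(7, pk_parameters(body_mass = 1), 0), 7 / 5)
  # monotone decay after the initial distribution-dominated fall
  t <- seq(0, 6, by = 0.05)
  c_t <- analytic_bolus(10.5, p, t)
  expect_true(all(diff(c_t) < 0))
  expect_error(analytic_bolus(10.5, p, -1), "non-negative")
})

test_that("empty schedules give identically zero profiles", {
  p <- pk_parameters()
  prof <- simulate_profile(infusion_schedule(numeric(0), dose_ug = 1), p,
                           grid_resolution = 30)
  expect_true(all(prof$conc_ng_ml == 0))
  expect_true(all(prof$infused_ug == 0))
  m <- exposure_metrics(prof)
  expect_equal(m$peak_conc, 0)
  expect_equal(m$auc, 0)
})

test_that("numerical simulator matches the analytic oracle for a bolus", {
  p <- pk_parameters()
  prof <- simulate_profile(infusion_schedule(0, dose_ug = 10.5), p,
                           grid_resolution = 5, t_end = 180)
  expect_equal(prof$conc_ng_ml[1], 6, tolerance = 1e-9)
  ana <- analytic_bolus(10.5, p, prof$time_min / 60)
  rel <- abs(prof$conc_ng_ml - ana) / pmax(ana, 1e-9)
  expect_lt(max(rel), 1e-6)
})

test_that("superposition, mass balance and non-negativity hold on random schedules", {
  p <- pk_parameters()
  set.seed(7)
  for (i in 1:10) {
    a <- random_schedule(6)
    b <- random_schedule(6)
    u <- infusion_schedule(sort(c(a$times_min, b$times_min)),
                           dose_ug = c(a$dose_ug, b$dose_ug)[
                             order(c(a$times_min, b$times_min))])
    sim <- function(s) simulate_profile(s, p, grid_resolution = 15,
                                        t_end = 130,
                                        keep_event_times = FALSE)
    pa <- sim(a); pb <- sim(b); pu <- sim(u)
    expect_equal(pu$time_min, pa$time_min)
    sum_ab <- pa$conc_ng_ml + pb$conc_ng_ml
    expect_lt(max(abs(pu$conc_ng_ml - sum_ab)) / max(pu$conc_ng_ml), 1e-6)
    total <- pu$central_ug + pu$peripheral_ug + pu$eliminated_ug
    expect_lt(max(abs(total - pu$infused_ug)) / max(pu$infused_ug), 1e-6)
    expect_true(all(pu$conc_ng_ml >= 0) && all(pu$peripheral_ug >= 0))
  }
})

test_that("exposure metrics recover the closed-form AUC and scale with dose", {
  p <- pk_parameters()
  prof <- simulate_profile(infusion_schedule(0, dose_ug = 10.5), p,
                           grid_resolution = 10, t_end = 1440)
  m <- exposure_metrics(prof, c(0, 1440))
  # AUC to infinity = dose / (k_el * Vc) = 10.5/1.4 ug*h/l = 450 ng*min/ml
  expect_equal(m$auc, 450, tolerance = 2e-3)
  expect_equal(m$peak_conc, 6, tolerance = 1e-8)
  expect_equal(m$peak_time, 0)

  prof2 <- simulate_profile(infusion_schedule(0, dose_ug = 21), p,
                            grid_resolution = 10, t_end = 1440)
  m2 <- exposure_metrics(prof2, c(0, 1440))
  expect_equal(m2$peak_conc, 2 * m$peak_conc, tolerance = 1e-8)
  expect_equal(m2$auc, 2 * m$auc, tolerance = 1e-8)

  expect_error(exposure_metrics(prof, c(10, 10)), "increasing")
  expect_error(exposure_metrics(prof, c(0, 2000)), "within")
})

test_that("a 2-s zero-order infusion is equivalent to a bolus at these time constants", {
  p <- pk_parameters()
  sched <- infusion_schedule(0, dose_ug = 10.5)
  pb <- simulate_profile(sched, p, grid_resolution = 1, t_end = 30)
  pi <- simulate_profile(sched, p, grid_resolution = 1, t_end = 30,
                         mode = "infusion")
  expect_lt(abs(max(pi$conc_ng_ml) / max(pb$conc_ng_ml) - 1), 0.005)
  # total drug delivered identical
  expect_equal(max(pi$infused_ug), max(pb$infused_ug))
})

test_that("clearance is the derived k_el * Vc consistency quantity", {
  expect_equal(derive_clearance(pk_parameters()), 1.4)
  expect_equal(suppressWarnings(
    derive_clearance(pk_parameters(body_mass = 1))), 4)
  expect_warning(derive_clearance(pk_parameters(body_mass = 1)),
                 "deviates")
  p <- pk_parameters(vc_per_kg = 1.4, k_el = 1, body_mass = 1,
                     clearance = 1.4)
  expect_equal(derive_clearance(p), 1.4)
})

test_that("invalid schedules and parameters are rejected", {
  expect_error(infusion_schedule(c(5, 1), dose_ug = 1), "non-decreasing")
  expect_error(infusion_schedule(-1, dose_ug = 1), "negative")
  expect_error(infusion_schedule(0, dose_ug = 0), "positive")
  expect_error(pk_parameters(k_el = -0.5), "positive")
  expect_error(pk_parameters(vc_per_kg = 0), "positive")
})

test_that("infusion schedules round-trip through delimited text", {
  sched <- reference_session_schedule("standard")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_min = sched$times_min,
                              dose_ug_per_kg = 30),
                   path, row.names = FALSE)
  back <- read_infusion_schedule(path, body_mass = 0.35)
  expect_equal(back$times_min, sched$times_min)
  expect_equal(back$dose_ug, sched$dose_ug)
})
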