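# Evoked dopamine transients: simulation limits, oracle equivalence,
# parameter recovery, protocol curves and electrode calibration.

test_that("without uptake a pulse deposits exactly da_per_pulse", {
  p <- mm_params(vmax = 1e-9, da_per_pulse = 0.8)
  tr <- simulate_trace(p, stim_pattern(), duration = 2, dt = 0.01)
  pk <- peak_da(tr)
  expect_equal(pk$peak_um, 0.8, tolerance = 1e-6)
  # no decay after the pulse
  post <- tr$da_um[tr$time_s >= 0.5]
  expect_lt(max(post) - min(post), 1e-6)
})

test_that("well below km the decay is exponential with rate vmax/km", {
  vmax <- 2; km <- 0.16
  p <- mm_params(vmax = vmax, km = km, da_per_pulse = 0.001 * km)
  tr <- simulate_trace(p, stim_pattern(onset_s = 0.1), duration = 0.5,
                       dt = 0.001)
  sel <- tr$time_s >= 0.1 & tr$time_s <= 0.25 & tr$da_um > 0
  slope <- stats::coef(stats::lm(log(tr$da_um[sel]) ~ tr$time_s[sel]))[2]
  expect_equal(unname(slope), -vmax / km, tolerance = 0.01)
})

test_that("a fast train with negligible uptake sums pulses linearly", {
  p <- mm_params(vmax = 1e-9, da_per_pulse = 0.5)
  tr <- simulate_trace(p, stim_pattern(n_pulses = 4, frequency = 100),
                       duration = 2, dt = 0.005)
  expect_equal(peak_da(tr)$peak_um, 4 * 0.5, tolerance = 1e-6)
})

test_that("simulated traces match a brute-force explicit-Euler oracle", {
  p <- mm_params(vmax = 2, da_per_pulse = 1)
  stim <- stim_pattern(n_pulses = 4, frequency = 30)
  tr <- simulate_trace(p, stim, duration = 5, dt = 0.01)
  orc <- euler_mm_trace(2, 0.16, 1, stim$pulse_times, 5, dt = 1e-4)
  at <- round(tr$time_s / 1e-4) + 1
  expect_lt(max(abs(tr$da_um - orc$da[at])), 1e-3)
})

test_that("traces are non-negative and uptake monotonicity holds", {
  set.seed(13)
  for (i in 1:5) {
    p <- mm_params(vmax = runif(1, 0.5, 6),
                   da_per_pulse = runif(1, 0.2, 3))
    tr <- simulate_trace(p, stim_pattern(n_pulses = 4, frequency = 10),
                         duration = 3, dt = 0.01)
    expect_true(all(tr$da_um >= 0))
  }
  lo <- simulate_trace(mm_params(vmax = 1, da_per_pulse = 1),
                       stim_pattern(), 3, 0.01)
  hi <- simulate_trace(mm_params(vmax = 4, da_per_pulse = 1),
                       stim_pattern(), 3, 0.01)
  expect_true(all(hi$da_um <= lo$da_um + 1e-12))
  expect_lte(peak_da(hi)$peak_um, peak_da(lo)$peak_um)
})

test_that("too-coarse sampling of a train is rejected", {
  p <- mm_params(vmax = 2, da_per_pulse = 1)
  expect_error(simulate_trace(p, stim_pattern(n_pulses = 4,
                                              frequency = 100),
                              duration = 2, dt = 0.1), "too coarse")
})

test_that("noiseless traces round-trip through the MM fit", {
  p <- mm_params(vmax = 2.4, da_per_pulse = 1.1)
  for (stim in list(stim_pattern(),
                    stim_pattern(n_pulses = 4, frequency = 30))) {
    tr <- simulate_trace(p, stim, duration = 3, dt = 0.01)
    fit <- fit_mm(tr)
    expect_lt(abs(fit$params$vmax / p$vmax - 1), 1e-3)
    expect_lt(abs(fit$params$da_per_pulse / p$da_per_pulse - 1), 1e-3)
  }
  flat <- fscv_trace(seq(0, 2, 0.01), numeric(201), stim_pattern())
  expect_error(fit_mm(flat), "no signal")
})

test_that("peak detection handles zero traces and multi-pulse dominance", {
  z <- fscv_trace(seq(0, 2, 0.1), numeric(21), stim_pattern())
  pk <- peak_da(z)
  expect_equal(pk$peak_um, 0)
  expect_equal(pk$peak_time_s, 0.5)  # window start = first pulse
  p <- mm_params(vmax = 2, da_per_pulse = 1)
  single <- simulate_trace(p, stim_pattern(), 3, 0.01)
  train <- simulate_trace(p, stim_pattern(n_pulses = 4, frequency = 100),
                          3, 0.005)
  expect_gte(peak_da(train)$peak_um, peak_da(single)$peak_um)
})

test_that("intensity curves normalize to their own maximum", {
  p <- mm_params(vmax = 2, da_per_pulse = 1)
  tr <- simulate_trace(p, stim_pattern(), 2, 0.01)
  same <- list(tr, tr, tr)
  cur <- intensity_curve(same, intensities = c(2, 5, 10))
  expect_equal(cur$normalized, rep(1, 3))
  expect_error(intensity_curve(same, intensities = c(2, 2, 10)),
               "duplicate")
  # saturating generator produces a monotone curve with max 1
  ds <- generate_fscv_dataset(n_slices = 1, noise_sd = 0, jitter_cv = 0,
                              seed = 2, duration = 2)
  sl <- ds$slices[[1]]
  cur2 <- intensity_curve(sl$intensity$traces, sl$intensity$intensities)
  expect_equal(max(cur2$normalized), 1)
  expect_true(all(diff(cur2$peak_um) >= -1e-9))
})

test_that("frequency response is expressed as percent of single-pulse release", {
  p <- mm_params(vmax = 2, da_per_pulse = 1)
  single <- simulate_trace(p, stim_pattern(), 3, 0.005)
  fr_same <- frequency_response(single, list(single), frequencies = 30)
  expect_equal(fr_same$percent_single_pulse, 100)
  p0 <- mm_params(vmax = 1e-9, da_per_pulse = 1)
  s0 <- simulate_trace(p0, stim_pattern(), 3, 0.005)
  t0 <- simulate_trace(p0, stim_pattern(n_pulses = 4, frequency = 100),
                       3, 0.005)
  expect_equal(frequency_response(s0, list(t0))$percent_single_pulse, 400,
               tolerance = 1e-6)
  # residual inter-pulse dopamine keeps trains at or above 100%
  trains <- lapply(c(3, 10, 30, 100), function(f)
    simulate_trace(p, stim_pattern(n_pulses = 4, frequency = f), 3, 0.005))
  fr <- frequency_response(single, trains)
  expect_true(all(fr$percent_single_pulse >= 100 - 1e-6))
  expect_error(frequency_response(NULL, trains), "reference")
})

test_that("electrode calibration recovers exact and noisy linear sensitivities", {
  tab <- data.frame(bg_current = c(100, 150, 200, 250, 300),
                    sensitivity_na_per_um = 2 + 0.01 * c(100, 150, 200,
                                                         250, 300))
  mod <- calibrate_electrode(tab)
  expect_equal(unname(stats::coef(mod$model)), c(2, 0.01),
               tolerance = 1e-9)
  expect_equal(predict(mod, data.frame(bg_current = 200)), 4)
  # applying the model inverts current to concentration
  tr <- apply_calibration(seq(0, 1, 0.1), rep(8, 11), mod,
                          data.frame(bg_current = 200))
  expect_equal(tr$da_um, rep(2, 11))

  set.seed(31)
  n <- 40
  bg <- runif(n, 80, 350)
  tab2 <- data.frame(bg_current = bg,
                     sensitivity_na_per_um = 1.5 + 0.012 * bg +
                       rnorm(n, 0, 0.05))
  mod2 <- calibrate_electrode(tab2)
  se <- summary(mod2$model)$coefficients[, "Std. Error"]
  expect_lt(abs(stats::coef(mod2$model)[2] - 0.012), 4 * se[2])

  tab3 <- data.frame(a = 1:6, b = 2 * (1:6),
                     sensitivity_na_per_um = 3 + 0.1 * (1:6))
  expect_error(calibrate_electrode(tab3), "collinear")
  expect_error(calibrate_electrode(tab[1:2, ]), "rows")
})

test_that("nicotine modulation curves normalize to baseline and flag flat slices", {
  doses <- 1e-9 * 10^(seq(0, 2, by = 0.5))
  flat <- nicotine_modulation_curve(1.2, doses, rep(1.2, length(doses)))
  expect_true(flat$flat)
  expect_true(is.na(flat$ic50))

  rel_true <- nicodose:::hill_value(doses, 1e-8, 1,
                                    direction = "inhibition")
  res <- nicotine_modulation_curve(2, doses, 2 * rel_true)
  expect_false(res$flat)
  expect_equal(res$series$response, rel_true)
  expect_lt(abs(res$ic50 / 1e-8 - 1), 1e-3)
  expect_error(nicotine_modulation_curve(0, doses, rel_true), "positive")

  # slices generated with a higher true midpoint yield a higher group mean
  set.seed(51)
  group_ic50 <- function(true_ic50, n = 4) {
    mean(vapply(seq_len(n), function(i) {
      rel <- nicodose:::hill_value(doses, true_ic50 * exp(rnorm(1, 0, 0.1)),
                                   1, direction = "inhibition") +
        rnorm(length(doses), 0, 0.02)
      nicotine_modulation_curve(1, doses, pmax(rel, 0))$ic50
    }, numeric(1)))
  }
  expect_lt(group_ic50(5e-9), group_ic50(3e-8))
})
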