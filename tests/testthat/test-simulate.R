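test_that("identical configurations give bit-identical traces", {
  cfg <- short_sim_config(seed = 5)
  a <- simulate_shark_trial(cfg)
  b <- simulate_shark_trial(cfg)
  expect_identical(a$oxygen_trace$o2_conc, b$oxygen_trace$o2_conc)
  expect_identical(a$blanks$pre$o2_conc, b$blanks$pre$o2_conc)
  expect_identical(a$truth, b$truth)
  # different seed: same schedule, different noise
  c2 <- simulate_shark_trial(short_sim_config(seed = 6))
  expect_identical(a$schedule$cycles, c2$schedule$cycles)
  expect_false(identical(a$oxygen_trace$o2_conc, c2$oxygen_trace$o2_conc))
})

test_that("noiseless steady state yields the analytic slope in every window", {
  cfg <- sim_config(sensor_noise_sd = 0, chase_boost = 1,
                    background_rate_start = 0, background_rate_end = 0,
                    hypoxia_step_schedule = NULL, normoxia_hours = 3,
                    accelerometer = FALSE)
  tr <- simulate_shark_trial(cfg)
  recs <- fit_mo2_records(tr$oxygen_trace, tr$schedule, tr$spec,
                          tr$conditions)
  expect_equal(recs$mo2, rep(150, nrow(recs)), tolerance = 1e-9)
  expect_equal(recs$slope_b,
               rep(-150 * 5 / (1500 - 5) / 3600, nrow(recs)),
               tolerance = 1e-9)
})

test_that("mass balance holds for every window of a noiseless trial", {
  cfg <- sim_config(sensor_noise_sd = 0, chase_boost = 1,
                    background_rate_start = 5, background_rate_end = 12,
                    hypoxia_step_schedule = NULL, normoxia_hours = 4,
                    accelerometer = FALSE)
  tr <- simulate_shark_trial(cfg)
  recs <- fit_mo2_records(tr$oxygen_trace, tr$schedule, tr$spec,
                          tr$conditions)
  dur_h <- 4
  bg <- function(t_h) 5 + (12 - 5) * t_h / dur_h
  for (i in seq_len(nrow(recs))) {
    # the 1-Hz integrator advances on left endpoints, so the OLS slope of
    # the quadratic oxygen path equals the rate half a sample before mid
    expected <- 150 * 5 + bg((recs$mid_time[i] - 0.5) / 3600)
    measured <- -recs$slope_b[i] * 3600 * tr$spec$effective_volume
    expect_equal(measured, expected, tolerance = 1e-9)
  }
})

test_that("background-corrected records match the generating rate", {
  cfg <- sim_config(sensor_noise_sd = 0, chase_boost = 1,
                    background_rate_start = 5, background_rate_end = 12,
                    hypoxia_step_schedule = NULL, normoxia_hours = 4,
                    accelerometer = FALSE)
  tr <- simulate_shark_trial(cfg)
  out <- recover_trial(tr)
  expect_equal(out$records$mo2, rep(150, nrow(out$records)),
               tolerance = 1e-6)
})

test_that("blank runs decline at the interpolated background rate", {
  cfg <- sim_config(sensor_noise_sd = 0, background_rate_start = 5,
                    background_rate_end = 15, normoxia_hours = 20,
                    hypoxia_step_schedule = data.frame(
                      target_sat = c(60, 40), hold_hours = 5),
                    accelerometer = FALSE)
  # trial spans 30 h, so the background runs 5 -> 15 mg O2/h over it
  bl <- simulate_blank_run(cfg, at_time = 15)
  rate <- fit_blank_rate(bl, tank_volume = 1500)
  expect_equal(rate$tank_rate, 10, tolerance = 1e-9)
  bl0 <- simulate_blank_run(cfg, at_time = 0)
  expect_equal(fit_blank_rate(bl0, 1500)$tank_rate, 5, tolerance = 1e-9)
  # zero background -> zero slope up to noise (noiseless here: exact)
  cfg0 <- sim_config(sensor_noise_sd = 0, background_rate_start = 0,
                     background_rate_end = 0, accelerometer = FALSE)
  expect_equal(fit_blank_rate(simulate_blank_run(cfg0, 2), 1500)$tank_rate,
               0, tolerance = 1e-12)
  expect_error(simulate_blank_run(cfg, 1, duration_h = -1), "positive")
})

test_that("acceleration signal is a calibrated sinusoid with working stops", {
  cfg <- sim_config(tailbeat_freq_base = 1.0, tailbeat_amp_base = 0.5,
                    accelerometer = TRUE)
  sig <- simulate_accel_signal(cfg, duration = 120)
  ser <- split_static_dynamic(sig)
  interior <- !ser$edge
  ref <- 0.5 * sin(2 * pi * cumsum(rep(1, nrow(sig))) / 25)
  expect_equal(ser$dyn_z[interior], ref[interior], tolerance = 0.02)
  # stop bout silences the dynamic component
  cfg2 <- sim_config(stop_bouts = data.frame(start = 600, duration = 60))
  sig2 <- simulate_accel_signal(cfg2, duration = 1200)
  ser2 <- split_static_dynamic(sig2)
  inside <- ser2$time > 605 & ser2$time < 655
  expect_lt(max(abs(ser2$dyn_z[inside])), 1e-6)
  outside <- ser2$time > 100 & ser2$time < 500
  expect_gt(stats::sd(ser2$dyn_z[outside]), 0.1)
  expect_error(sim_config(stop_bouts = data.frame(start = c(0, 30),
                                                  duration = c(60, 10))),
               "overlapping")
})

test_that("wavelet frequency estimate matches the generating tailbeat", {
  cfg <- sim_config(tailbeat_freq_base = 0.8, tailbeat_amp_base = 0.3)
  sig <- simulate_accel_signal(cfg, duration = 180)
  ser <- wavelet_tbf_tbaa(compute_odba(split_static_dynamic(sig)))
  mid <- ser$time > 20 & ser$time < 160
  expect_equal(mean(ser$tbf[mid]), 0.8, tolerance = 0.02 / 0.8)
})

test_that("hypoxia protocol produces enough sub-critical periods and truth is coherent", {
  cfg <- sim_config(seed = 2, accelerometer = FALSE)
  tr <- simulate_shark_trial(cfg)
  expect_gte(tr$truth$n_sub_ccrit_periods, 3)
  expect_equal(tr$truth$true_as,
               tr$truth$true_mmr - tr$truth$true_mrmr)
  expect_gte(tr$truth$true_mmr, tr$truth$true_mrmr)
  sat_conc <- o2_saturation_concentration(tr$conditions)
  expect_equal(tr$truth$true_scrit, tr$truth$true_ccrit / sat_conc)
  expect_equal(tr$truth$true_pcrit,
               tr$truth$true_scrit * ambient_po2(tr$conditions))
  # per-period truth declines below the breakpoint
  sub <- tr$truth$per_period[tr$truth$per_period$sub_ccrit, ]
  expect_true(all(sub$true_mo2 < tr$truth$true_mrmr))
})

test_that("invalid protocols are rejected", {
  expect_error(sim_config(hypoxia_step_schedule = data.frame(
    target_sat = c(60, 70), hold_hours = 1)), "decreasing")
  expect_error(sim_config(hypoxia_step_schedule = data.frame(
    target_sat = c(60, 40), hold_hours = c(1, 0.2))),
    "final hypoxia step")
  expect_error(sim_config(respirometer_volume = 4, animal_mass = 5),
               "effective volume")
})
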