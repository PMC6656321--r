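fs <- 25

test_that("static/dynamic decomposition is exact and handles canonical inputs", {
  t <- (0:(60 * fs - 1)) / fs
  # constant input: static = input, dynamic = 0
  tr <- accel_trace(t, rep(0, length(t)), rep(0, length(t)),
                    rep(-1, length(t)))
  ser <- split_static_dynamic(tr)
  expect_equal(ser$static_z, rep(-1, length(t)))
  expect_equal(ser$dyn_z, rep(0, length(t)))
  # linear ramp: interior static equals the ramp, dynamic 0
  ramp <- 0.001 * t
  ser <- split_static_dynamic(accel_trace(t, ramp, ramp, ramp))
  interior <- !ser$edge
  expect_equal(ser$static_x[interior], ramp[interior], tolerance = 1e-12)
  expect_equal(ser$dyn_x[interior], rep(0, sum(interior)), tolerance = 1e-12)
  # 1-Hz sinusoid: interior static ~ 0 (integer cycles in the 3-s window)
  z <- 0.5 * sin(2 * pi * 1 * t)
  ser <- split_static_dynamic(accel_trace(t, 0 * t, 0 * t, z))
  expect_lt(max(abs(ser$static_z[!ser$edge])), 0.01)
  expect_equal(ser$dyn_z[!ser$edge], z[!ser$edge], tolerance = 0.01)
  # decomposition identity holds everywhere, to machine precision
  expect_equal(ser$static_z + ser$dyn_z, z)
  expect_error(split_static_dynamic(accel_trace(t[1:10], 1:10 * 0, 1:10 * 0,
                                                1:10 * 0)), "shorter")
})

test_that("ODBA matches the rectified-sinusoid closed form and is homogeneous", {
  t <- (0:(100 * fs - 1)) / fs
  ser <- activity_series(t, dyn_x = 0 * t, dyn_y = 0 * t,
                         dyn_z = 0.5 * sin(2 * pi * t))
  ser <- compute_odba(ser)
  expect_equal(mean(ser$odba), 2 * 0.5 / pi, tolerance = 0.002)
  # zero dynamic -> zero
  z0 <- compute_odba(activity_series(t, 0 * t, 0 * t, 0 * t))
  expect_equal(z0$odba, rep(0, length(t)))
  # homogeneity of degree 1
  ser2 <- activity_series(t, dyn_x = 0 * t, dyn_y = 0 * t,
                          dyn_z = 1.0 * sin(2 * pi * t))
  expect_equal(compute_odba(ser2)$odba, 2 * ser$odba)
})

test_that("wavelet ridge recovers sinusoid frequency and amplitude", {
  t <- (0:(120 * fs - 1)) / fs
  for (A in c(0.1, 0.3, 0.6)) {
    for (f in c(0.5, 1, 2)) {
      ser <- activity_series(t, 0 * t, 0 * t, A * sin(2 * pi * f * t))
      ser <- wavelet_tbf_tbaa(ser)
      mid <- ser$time > 10 & ser$time < 110
      expect_equal(mean(ser$tbf[mid]), f, tolerance = 0.02)
      expect_equal(mean(ser$tbaa[mid]), A, tolerance = 0.05)
    }
  }
})

test_that("wavelet ridge tracks a frequency step", {
  t <- (0:(240 * fs - 1)) / fs
  f_seg <- ifelse(t < 120, 0.6, 1.2)
  phase <- 2 * pi * cumsum(f_seg) / fs
  ser <- activity_series(t, 0 * t, 0 * t, 0.3 * sin(phase))
  ser <- wavelet_tbf_tbaa(ser)
  seg1 <- ser$time > 10 & ser$time < 110
  seg2 <- ser$time > 130 & ser$time < 230
  expect_equal(mean(ser$tbf[seg1]), 0.6, tolerance = 0.05 / 0.6)
  expect_equal(mean(ser$tbf[seg2]), 1.2, tolerance = 0.05 / 1.2)
})

test_that("zero signal yields zero amplitude and undefined frequency", {
  t <- (0:(30 * fs - 1)) / fs
  ser <- wavelet_tbf_tbaa(activity_series(t, 0 * t, 0 * t, 0 * t))
  expect_true(all(is.na(ser$tbf)))
  expect_equal(ser$tbaa, rep(0, length(t)), tolerance = 1e-9)
  expect_error(
    wavelet_tbf_tbaa(activity_series(t, 0 * t, 0 * t, 0 * t),
                     band = c(0.2, 20)), "Nyquist")
})

test_that("swim-stop bouts are detected from amplitude silences", {
  t <- (0:(1200 * fs - 1)) / fs
  gate <- !(t >= 600 & t < 660)
  ser <- activity_series(t, 0 * t, 0 * t,
                         0.3 * sin(2 * pi * t) * gate)
  ser <- wavelet_tbf_tbaa(ser)
  bouts <- detect_swimming_stops(ser)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$duration, 60, tolerance = 3)
  expect_equal(bouts$start, 600, tolerance = 3)
  # wavelet power inside the silence is near zero
  inside <- ser$time > 610 & ser$time < 650
  expect_lt(max(ser$tbaa[inside]), 0.01)
  # continuous swimming: no bouts; full silence: one spanning bout
  swim <- wavelet_tbf_tbaa(activity_series(t, 0 * t, 0 * t,
                                           0.3 * sin(2 * pi * t)))
  expect_equal(nrow(detect_swimming_stops(swim)), 0)
  silent <- wavelet_tbf_tbaa(activity_series(t, 0 * t, 0 * t, 0 * t))
  allq <- detect_swimming_stops(silent)
  expect_equal(nrow(allq), 1)
  expect_equal(allq$duration, 1200, tolerance = 1)
})

test_that("per-period aggregation is mean-consistent and stop-aware", {
  sched <- regular_schedule(2)
  t <- (0:(2 * 2700 * fs - 1)) / fs
  # half swimming, half stopped within each recording window
  rs1 <- 180; re1 <- 900
  gate <- rep(TRUE, length(t))
  for (cyc in 0:1) {
    mid <- cyc * 2700 + (rs1 + re1) / 2
    gate[t >= mid & t < cyc * 2700 + re1] <- FALSE
  }
  ser <- activity_series(t, 0 * t, 0 * t, 0.3 * sin(2 * pi * t) * gate)
  ser <- compute_odba(wavelet_tbf_tbaa(ser))
  agg <- aggregate_by_period(ser, sched)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$mean_tbf, c(1, 1), tolerance = 0.02)
  expect_equal(agg$stop_fraction, c(0.5, 0.5), tolerance = 0.03)
  # constant metrics aggregate to the constant
  ser2 <- ser
  ser2$tbf <- 1.3; ser2$tbaa <- 0.25; ser2$odba <- 0.4
  agg2 <- aggregate_by_period(ser2, sched)
  expect_equal(agg2$mean_tbf, c(1.3, 1.3))
  expect_equal(agg2$mean_odba, c(0.4, 0.4))
  expect_equal(agg2$stop_fraction, c(0, 0))
})

test_that("acceleration trace validation enforces uniform sampling and range", {
  expect_error(accel_trace(c(0, 0.04, 0.1), rep(0, 3), rep(0, 3), rep(0, 3)),
               "uniform")
  t <- (0:99) / 25
  expect_error(accel_trace(t, rep(20, 100), rep(0, 100), rep(0, 100)),
               "16 g")
})
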