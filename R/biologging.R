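#' Triaxial accelerometer trace
#'
#' @param time Seconds since trial start.
#' @param ax,ay,az Acceleration per axis in g (z = lateral sway axis).
#' @param sample_rate Sampling rate in Hz. Default 25.
#' @return A data frame of class `accel_trace`.
#' @export
accel_trace <- function(time, ax, ay, az, sample_rate = 25) {
  n <- length(time)
  stopifnot(length(ax) == n, length(ay) == n, length(az) == n, n >= 2L)
  dt <- diff(time)
  if (any(abs(dt - 1 / sample_rate) > 0.01 / sample_rate))
    stop("sampling must be uniform at sample_rate within 1%")
  if (max(abs(c(ax, ay, az))) >= 16)
    stop("acceleration outside the +/-16 g logger range")
  out <- data.frame(time = time, ax = ax, ay = ay, az = az)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("accel_trace", "data.frame")
  out
}

#' Split raw acceleration into static and dynamic components
#'
#' The static (gravity) component per axis is a centred moving average over a
#' smoothing window (default 3 s, i.e. 75 samples at 25 Hz — appropriate for
#' a tailbeat cycle near 1 Hz); the dynamic component is the raw signal minus
#' the static one, so the decomposition is exact by construction. Edge
#' windows are truncated and flagged.
#'
#' @param trace An [accel_trace()].
#' @param window Smoothing window length in seconds. Default 3.
#' @return A data frame of class `activity_series` with `time`,
#'   `static_x/y/z`, `dyn_x/y/z` and an `edge` flag for samples whose
#'   smoothing window was truncated.
#' @export
split_static_dynamic <- function(trace, window = 3) {
  stopifnot(inherits(trace, "accel_trace"))
  fs <- attr(trace, "sample_rate")
  width <- as.integer(round(window * fs))
  if (width < 3L) stop("window x sample_rate must cover at least 3 samples")
  if (nrow(trace) < width) stop("trace is shorter than one smoothing window")
  half <- width %/% 2L
  n <- nrow(trace)
  out <- data.frame(
    time = trace$time,
    static_x = moving_average(trace$ax, width),
    static_y = moving_average(trace$ay, width),
    static_z = moving_average(trace$az, width)
  )
  out$dyn_x <- trace$ax - out$static_x
  out$dyn_y <- trace$ay - out$static_y
  out$dyn_z <- trace$az - out$static_z
  out$edge <- seq_len(n) <= half | seq_len(n) > n - half
  attr(out, "sample_rate") <- fs
  class(out) <- c("activity_series", "data.frame")
  out
}

#' Build an activity series from known components
#'
#' Constructor used when the static/dynamic decomposition is already known
#' (constructed signals, calibration): wraps dynamic (and optionally static)
#' components into the `activity_series` layout that [compute_odba()] and
#' [wavelet_tbf_tbaa()] consume.
#'
#' @param time Seconds.
#' @param dyn_x,dyn_y,dyn_z Dynamic components, g.
#' @param static_x,static_y,static_z Static components, g. Default 0.
#' @param sample_rate Hz. Default 25.
#' @return An `activity_series` data frame.
#' @export
activity_series <- function(time, dyn_x, dyn_y, dyn_z,
                            static_x = 0, static_y = 0, static_z = 0,
                            sample_rate = 25) {
  n <- length(time)
  out <- data.frame(
    time = time,
    static_x = rep_len(static_x, n), static_y = rep_len(static_y, n),
    static_z = rep_len(static_z, n),
    dyn_x = dyn_x, dyn_y = dyn_y, dyn_z = dyn_z,
    edge = FALSE)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("activity_series", "data.frame")
  out
}

#' Overall dynamic body acceleration
#'
#' ODBA per sample is the sum of the absolute dynamic components of the three
#' axes, the standard locomotor-effort proxy.
#'
#' @param series An `activity_series` from [split_static_dynamic()].
#' @return The series with an `odba` column added.
#' @export
compute_odba <- function(series) {
  stopifnot(all(c("dyn_x", "dyn_y", "dyn_z") %in% names(series)))
  series$odba <- abs(series$dyn_x) + abs(series$dyn_y) + abs(series$dyn_z)
  series
}

# Analytic Morlet continuous wavelet transform of a real signal, FFT-based.
# Returns the complex transform (n x n_freq) for the requested frequencies.
# Scale-to-frequency uses the energy-peak convention f = omega0 / (2 pi s):
# the calibrated amplitude A * exp(-(s*wa - omega0)^2 / 2) of a sinusoid at
# frequency wa is then maximal exactly at the grid frequency equal to wa.
# Normalisation: for x = A cos(2 pi f t), |W| at the ridge equals
# (A/2) * pi^(-1/4) * sqrt(2 pi s / dt), which the callers invert to get A.
morlet_cwt <- function(x, dt, freqs, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xhat <- stats::fft(c(x, rep(0, npad - n)))
  omega <- 2 * pi * c(0:(npad / 2), -((npad / 2 - 1):1)) / (npad * dt)
  scales <- omega0 / (2 * pi * freqs)
  w <- matrix(0 + 0i, nrow = n, ncol = length(freqs))
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi_hat <- numeric(npad)
    pos <- omega > 0
    psi_hat[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    w[, j] <- (stats::fft(xhat * psi_hat, inverse = TRUE) / npad)[seq_len(n)]
  }
  attr(w, "freqs") <- freqs
  attr(w, "scales") <- scales
  attr(w, "amp_factor") <- 2 * pi^(1 / 4) / sqrt(2 * pi * scales / dt)
  w
}

#' Tailbeat frequency and amplitude by wavelet ridge extraction
#'
#' Continuous analytic Morlet wavelet transform of the dynamic z-axis
#' (lateral sway) on a log-spaced frequency grid covering the tailbeat band.
#' Per sample, the ridge is the in-band frequency of maximum wavelet power,
#' refined by quadratic interpolation across neighbouring grid frequencies;
#' TBF is the ridge frequency and TBAA the amplitude-calibrated ridge
#' magnitude (a pure sinusoid of amplitude A returns TBAA = A). Samples whose
#' ridge amplitude falls below `min_amp` have TBF set to `NA` (no detectable
#' tailbeat).
#'
#' @param series An `activity_series` with `dyn_z` filled.
#' @param band Frequency band in Hz. Default c(0.2, 3).
#' @param voices Grid points per octave. Default 16.
#' @param omega0 Morlet nondimensional centre frequency. Default 6.
#' @param min_amp Amplitude floor (g) below which TBF is undefined.
#'   Default 0.02.
#' @param smooth_ridge Optional running-median length (samples, odd) applied
#'   to the ridge frequency; `NULL` (default) disables it.
#' @return The series with `tbf` (Hz) and `tbaa` (g) columns added.
#' @export
wavelet_tbf_tbaa <- function(series, band = c(0.2, 3), voices = 16,
                             omega0 = 6, min_amp = 0.02,
                             smooth_ridge = NULL) {
  stopifnot("dyn_z" %in% names(series))
  fs <- attr(series, "sample_rate")
  if (is.null(fs)) stop("series lacks a sample_rate attribute")
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie strictly inside (0, Nyquist)")
  n_oct <- log2(band[2] / band[1])
  freqs <- band[1] * 2^(seq(0, n_oct, length.out = max(2L, ceiling(n_oct * voices) + 1L)))
  w <- morlet_cwt(series$dyn_z, dt = 1 / fs, freqs = freqs, omega0 = omega0)
  amp <- sweep(Mod(w), 2, attr(w, "amp_factor"), `*`)
  j <- max.col(amp, ties.method = "first")
  n <- nrow(amp)
  rows <- seq_len(n)
  lf <- log(freqs)
  # quadratic interpolation of log-amplitude over log-frequency at the peak
  tbf <- freqs[j]
  tbaa <- amp[cbind(rows, j)]
  interior <- j > 1L & j < length(freqs)
  if (any(interior)) {
    ji <- j[interior]; ri <- rows[interior]
    a0 <- log(pmax(amp[cbind(ri, ji - 1L)], 1e-300))
    a1 <- log(pmax(amp[cbind(ri, ji)], 1e-300))
    a2 <- log(pmax(amp[cbind(ri, ji + 1L)], 1e-300))
    denom <- a0 - 2 * a1 + a2
    delta <- ifelse(abs(denom) > 1e-12, 0.5 * (a0 - a2) / denom, 0)
    delta <- pmax(pmin(delta, 0.5), -0.5)
    step <- lf[2] - lf[1]
    tbf[interior] <- exp(lf[ji] + delta * step)
    tbaa[interior] <- exp(a1 + 0.25 * (a2 - a0) * delta)
  }
  if (!is.null(smooth_ridge)) {
    tbf <- stats::runmed(tbf, k = smooth_ridge)
  }
  tbf[tbaa < min_amp] <- NA_real_
  series$tbf <- tbf
  series$tbaa <- tbaa
  series
}

#' Average activity metrics over each measurement period
#'
#' Means of TBF, TBAA and ODBA over every recording window of the schedule.
#' Samples with undefined TBF (no detectable tailbeat) are excluded from
#' `mean_tbf` and counted into `stop_fraction`.
#'
#' @param series An `activity_series` with `tbf`, `tbaa`, `odba` filled.
#' @param schedule A [trial_schedule()].
#' @return Data frame with `period_index`, `mean_tbf`, `mean_tbaa`,
#'   `mean_odba`, `stop_fraction`, `n_samples`.
#' @export
aggregate_by_period <- function(series, schedule) {
  stopifnot(inherits(schedule, "trial_schedule"),
            all(c("tbf", "tbaa", "odba") %in% names(series)))
  cycles <- schedule$cycles
  out <- list()
  for (i in seq_len(nrow(cycles))) {
    rs <- cycles$measure_start[i] + schedule$equilibration
    re <- rs + schedule$recording
    idx <- series$time >= rs & series$time < re
    if (!any(idx)) {
      warning(sprintf("no acceleration samples in recording window %d; dropped", i))
      next
    }
    tbf <- series$tbf[idx]
    out[[length(out) + 1L]] <- data.frame(
      period_index = i,
      mean_tbf = if (all(is.na(tbf))) NA_real_ else mean(tbf, na.rm = TRUE),
      mean_tbaa = mean(series$tbaa[idx]),
      mean_odba = mean(series$odba[idx]),
      stop_fraction = mean(is.na(tbf)),
      n_samples = sum(idx)
    )
  }
  if (length(out) == 0L)
    return(data.frame(period_index = integer(), mean_tbf = numeric(),
                      mean_tbaa = numeric(), mean_odba = numeric(),
                      stop_fraction = numeric(), n_samples = integer()))
  do.call(rbind, out)
}

#' Detect swim-stop bouts
#'
#' Maximal intervals where the tailbeat amplitude stays below a threshold for
#' at least a minimum duration — the signature of an obligate ram ventilator
#' ceasing to swim.
#'
#' @param series An `activity_series` with `tbaa` filled.
#' @param amp_threshold TBAA threshold in g. Default 0.05.
#' @param min_duration Minimum bout length in seconds. Default 5.
#' @return Data frame with `start` (s), `duration` (s) per bout.
#' @export
detect_swimming_stops <- function(series, amp_threshold = 0.05,
                                  min_duration = 5) {
  stopifnot("tbaa" %in% names(series))
  quiet <- series$tbaa < amp_threshold
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fs <- attr(series, "sample_rate") %||% 25
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    dur <- r$lengths[k] / fs
    if (dur < min_duration) next
    out[[length(out) + 1L]] <- data.frame(
      start = series$time[starts[k]], duration = dur)
  }
  if (length(out) == 0L)
    return(data.frame(start = numeric(), duration = numeric()))
  do.call(rbind, out)
}

#' Per-period activity from a raw acceleration trace
#'
#' Convenience wrapper running the static/dynamic split, ODBA and the wavelet
#' ridge extraction window by window (each recording window is processed
#' independently, which keeps the transform cheap on long trials), then
#' aggregating per measurement period.
#'
#' @param trace An [accel_trace()].
#' @param schedule A [trial_schedule()].
#' @param window Static smoothing window, s. Default 3.
#' @param ... Passed to [wavelet_tbf_tbaa()].
#' @return As [aggregate_by_period()].
#' @export
activity_by_period <- function(trace, schedule, window = 3, ...) {
  stopifnot(inherits(trace, "accel_trace"),
            inherits(schedule, "trial_schedule"))
  fs <- attr(trace, "sample_rate")
  cycles <- schedule$cycles
  out <- list()
  for (i in seq_len(nrow(cycles))) {
    rs <- cycles$measure_start[i] + schedule$equilibration
    re <- rs + schedule$recording
    idx <- trace$time >= rs & trace$time < re
    if (sum(idx) < 3 * fs) {
      warning(sprintf("too few acceleration samples in window %d; dropped", i))
      next
    }
    sub <- trace[idx, , drop = FALSE]
    attr(sub, "sample_rate") <- fs
    class(sub) <- c("accel_trace", "data.frame")
    ser <- compute_odba(split_static_dynamic(sub, window = window))
    ser <- wavelet_tbf_tbaa(ser, ...)
    tbf <- ser$tbf
    out[[length(out) + 1L]] <- data.frame(
      period_index = i,
      mean_tbf = if (all(is.na(tbf))) NA_real_ else mean(tbf, na.rm = TRUE),
      mean_tbaa = mean(ser$tbaa),
      mean_odba = mean(ser$odba),
      stop_fraction = mean(is.na(tbf)),
      n_samples = nrow(ser)
    )
  }
  if (length(out) == 0L)
    return(data.frame(period_index = integer(), mean_tbf = numeric(),
                      mean_tbaa = numeric(), mean_odba = numeric(),
                      stop_fraction = numeric(), n_samples = integer()))
  do.call(rbind, out)
}
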