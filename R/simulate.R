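#' Simulation configuration for a synthetic respirometry trial
#'
#' Defines the full study protocol and the generating physiology for one
#' simulated trial: a chase-elevated metabolic rate recovering exponentially
#' toward the routine floor over ~20 h of normoxia, then a stepwise hypoxia
#' protocol during which the animal oxyregulates above the critical oxygen
#' concentration and oxyconforms (metabolic rate linear in oxygen) below it.
#' Oxygen dynamics follow a single well-mixed compartment: sealed recording
#' windows decline at (animal consumption + microbial background) / effective
#' volume; flushing relaxes the tank exponentially toward the reservoir.
#'
#' @param seed Integer RNG seed.
#' @param temperature Water temperature, degrees C. Default 28.
#' @param salinity Practical salinity, psu. Default 35.
#' @param barometric_pressure mmHg. Default 760.
#' @param respirometer_volume Tank volume, litres. Default 1500.
#' @param animal_mass Body mass, kg. Default 5.
#' @param animal_length Total length, cm. Default 98.
#' @param true_mrmr Routine metabolic floor, mg O2 kg-1 h-1. Default 150.
#' @param chase_boost Multiplicative elevation of metabolic rate at t = 0
#'   (end of the chase); >= 1. Default 2.2.
#' @param recovery_time_constant Exponential recovery time constant, h.
#'   Default 5 (recovery ~98% complete by the 20-h normoxia mark, matching a
#'   protocol sized to let the animal reach its routine floor overnight).
#' @param true_ccrit Critical oxygen concentration, mg l-1. Default 3.4.
#' @param conformity_slope Decline of metabolic rate per mg l-1 below
#'   `true_ccrit`, mg O2 kg-1 h-1 per mg l-1. Default 40.
#' @param hypoxic_effort Multiplicative elevation of the regulating metabolic
#'   rate during the hypoxia phase while oxygen is still above `true_ccrit`
#'   (ram ventilators swim harder to irrigate their gills as oxygen falls);
#'   regulation collapses to the oxyconforming line below `true_ccrit`.
#'   Default 1.1.
#' @param background_rate_start,background_rate_end Whole-tank microbial
#'   respiration at trial start/end, mg O2 h-1. Defaults 5 and 10.
#' @param sensor_noise_sd Gaussian sensor noise on recorded oxygen, mg l-1.
#'   Default 0.01 (1-Hz optical optode).
#' @param flush_minutes Flushing period, min (30-45). Default 30.
#' @param equilibration_minutes Equilibration interval, min. Default 3.
#' @param recording_minutes Recording span, min. Default 12.
#' @param normoxia_hours Normoxic phase length, h. Default 20.
#' @param hypoxia_step_schedule Data frame with `target_sat` (percent
#'   saturation, strictly decreasing) and `hold_hours`. Default steps
#'   80, 70, 60, 50, 40, 30% held 1.5 h each.
#' @param tailbeat_freq_base Tailbeat frequency at routine swimming, Hz.
#'   Default 1.0.
#' @param tailbeat_amp_base Tailbeat z-axis acceleration amplitude, g.
#'   Default 0.3.
#' @param stop_bouts Optional data frame with `start` and `duration`
#'   (seconds) zeroing the dynamic acceleration. Default none.
#' @param accelerometer Generate the acceleration trace? Default TRUE.
#' @param mixing_time_constant Flush-phase mixing time constant, s.
#'   Default 300.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       temperature = 28, salinity = 35,
                       barometric_pressure = 760,
                       respirometer_volume = 1500,
                       animal_mass = 5, animal_length = 98,
                       true_mrmr = 150, chase_boost = 2.2,
                       recovery_time_constant = 5,
                       true_ccrit = 3.4, conformity_slope = 40,
                       hypoxic_effort = 1.1,
                       background_rate_start = 5,
                       background_rate_end = 10,
                       sensor_noise_sd = 0.01,
                       flush_minutes = 30, equilibration_minutes = 3,
                       recording_minutes = 12, normoxia_hours = 20,
                       hypoxia_step_schedule = data.frame(
                         target_sat = c(80, 70, 60, 50, 40, 30),
                         hold_hours = 1.5),
                       tailbeat_freq_base = 1.0,
                       tailbeat_amp_base = 0.3,
                       stop_bouts = NULL,
                       accelerometer = TRUE,
                       mixing_time_constant = 300) {
  stopifnot(respirometer_volume > 0, animal_mass > 0, true_mrmr > 0,
            chase_boost >= 1, recovery_time_constant > 0, true_ccrit > 0,
            hypoxic_effort >= 1,
            conformity_slope >= 0, sensor_noise_sd >= 0,
            flush_minutes > 0, normoxia_hours >= 0,
            tailbeat_freq_base > 0, tailbeat_amp_base >= 0,
            mixing_time_constant > 0)
  if (respirometer_volume <= animal_mass * 1.0)
    stop("non-positive effective volume after subtracting the animal volume")
  if (!is.null(hypoxia_step_schedule) && nrow(hypoxia_step_schedule) > 0) {
    ts <- hypoxia_step_schedule$target_sat
    if (any(diff(ts) >= 0))
      stop("hypoxia steps must be strictly decreasing in percent saturation")
    if (any(hypoxia_step_schedule$hold_hours <= 0))
      stop("hypoxia hold durations must be positive")
    cycle_h <- (recording_minutes + equilibration_minutes + flush_minutes) / 60
    if (utils::tail(hypoxia_step_schedule$hold_hours, 1) < cycle_h)
      stop("protocol never reaches the final hypoxia step: its hold is ",
           "shorter than one flush/measure cycle")
  }
  if (!is.null(stop_bouts) && nrow(stop_bouts) > 1) {
    sb <- stop_bouts[order(stop_bouts$start), ]
    if (any(sb$start[-1] < (sb$start + sb$duration)[-nrow(sb)]))
      stop("overlapping stop bouts")
  }
  structure(
    list(seed = seed, temperature = temperature, salinity = salinity,
         barometric_pressure = barometric_pressure,
         respirometer_volume = respirometer_volume,
         animal_mass = animal_mass, animal_length = animal_length,
         true_mrmr = true_mrmr, chase_boost = chase_boost,
         recovery_time_constant = recovery_time_constant,
         true_ccrit = true_ccrit, conformity_slope = conformity_slope,
         hypoxic_effort = hypoxic_effort,
         background_rate_start = background_rate_start,
         background_rate_end = background_rate_end,
         sensor_noise_sd = sensor_noise_sd, flush_minutes = flush_minutes,
         equilibration_minutes = equilibration_minutes,
         recording_minutes = recording_minutes,
         normoxia_hours = normoxia_hours,
         hypoxia_step_schedule = hypoxia_step_schedule,
         tailbeat_freq_base = tailbeat_freq_base,
         tailbeat_amp_base = tailbeat_amp_base, stop_bouts = stop_bouts,
         accelerometer = accelerometer,
         mixing_time_constant = mixing_time_constant),
    class = "sim_config")
}

sim_conditions <- function(config) {
  gas_conditions(config$temperature, config$salinity,
                 config$barometric_pressure)
}

# reservoir percent-saturation target as a step function of time (s)
reservoir_sat <- function(config, t) {
  sat <- rep(100, length(t))
  steps <- config$hypoxia_step_schedule
  if (is.null(steps) || nrow(steps) == 0) return(sat)
  edges <- config$normoxia_hours * 3600 +
    cumsum(c(0, steps$hold_hours * 3600))
  for (k in seq_len(nrow(steps))) {
    sat[t >= edges[k] & t < edges[k + 1]] <- steps$target_sat[k]
  }
  sat[t >= utils::tail(edges, 1)] <- utils::tail(steps$target_sat, 1)
  sat
}

# whole-tank microbial background rate (mg O2/h) over trial time (h)
sim_background <- function(config, duration_h) {
  b0 <- config$background_rate_start
  b1 <- config$background_rate_end
  function(t_h) b0 + (b1 - b0) * t_h / duration_h
}

#' Simulate a complete respirometry + biologging trial
#'
#' Generates the oxygen trace (1 Hz), the 25-Hz acceleration trace, pre- and
#' post-trial blank runs and the full ground truth, under the protocol and
#' physiology in `config`. Identical configs (including seed) give
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulated_trial`: list with `oxygen_trace`,
#'   `accel_trace` (or NULL), `schedule`, `blanks` (pre/post traces with
#'   their trial-time midpoints in hours), `truth`, `spec`, `conditions`,
#'   `config`.
#' @export
simulate_shark_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cond <- sim_conditions(config)
  sat_conc <- o2_saturation_concentration(cond)
  spec <- respirometer_spec(config$animal_mass,
                            tank_volume = config$respirometer_volume)
  veff <- spec$effective_volume

  steps <- config$hypoxia_step_schedule
  duration_h <- config$normoxia_hours +
    if (is.null(steps)) 0 else sum(steps$hold_hours)
  duration_s <- round(duration_h * 3600)
  cycle_s <- (config$recording_minutes + config$equilibration_minutes +
                config$flush_minutes) * 60
  n_cycles <- floor(duration_s / cycle_s)
  if (n_cycles < 1L) stop("trial too short for a single flush/measure cycle")
  schedule <- regular_schedule(
    n_cycles,
    measure_minutes = config$recording_minutes + config$equilibration_minutes,
    flush_minutes = config$flush_minutes,
    equilibration = config$equilibration_minutes * 60,
    recording = config$recording_minutes * 60)

  tt <- 0:(duration_s - 1L)
  res_conc <- reservoir_sat(config, tt) / 100 * sat_conc
  base <- config$true_mrmr *
    (1 + (config$chase_boost - 1) * exp(-tt / 3600 / config$recovery_time_constant))
  bg_fun <- sim_background(config, duration_h)
  bg <- bg_fun(tt / 3600)
  # sealed (measurement) mask: within any measure window
  in_measure <- rep(FALSE, duration_s)
  for (i in seq_len(n_cycles)) {
    ms <- schedule$cycles$measure_start[i]
    me <- schedule$cycles$measure_end[i]
    in_measure[tt >= ms & tt < me] <- TRUE
  }
  relax <- 1 - exp(-1 / config$mixing_time_constant)

  o2 <- numeric(duration_s)
  mo2_inst <- numeric(duration_s)
  state <- sat_conc
  cs <- config$conformity_slope
  ccrit <- config$true_ccrit
  hypoxia_start <- config$normoxia_hours * 3600
  effort <- config$hypoxic_effort
  for (k in seq_len(duration_s)) {
    o2[k] <- state
    m <- if (state >= ccrit) {
      base[k] * (if (tt[k] >= hypoxia_start) effort else 1)
    } else {
      base[k] - cs * (ccrit - state)
    }
    if (m < 0) m <- 0
    mo2_inst[k] <- m
    d_cons <- (m * config$animal_mass + bg[k]) / veff / 3600
    state <- state - d_cons
    if (!in_measure[k]) state <- state + (res_conc[k] - state) * relax
    if (state < 0) state <- 0
  }
  obs <- o2 + stats::rnorm(duration_s, 0, config$sensor_noise_sd)
  obs[obs < 0] <- 0
  trace <- oxygen_trace(tt, obs, config$temperature, conditions = cond)

  # per-period ground truth over the recording windows
  rec_start <- schedule$cycles$measure_start + schedule$equilibration
  rec_end <- rec_start + schedule$recording
  per <- lapply(seq_len(n_cycles), function(i) {
    idx <- tt >= rec_start[i] & tt < rec_end[i]
    data.frame(period_index = i,
               true_mo2 = mean(mo2_inst[idx]),
               true_o2 = mean(o2[idx]),
               sub_ccrit = mean(o2[idx]) < ccrit)
  })
  per <- do.call(rbind, per)

  accel <- NULL
  if (isTRUE(config$accelerometer)) {
    rel <- ifelse(o2 >= ccrit, mo2_inst / config$true_mrmr, 1)
    accel <- simulate_accel_signal(config, duration = duration_s,
                                   mo2_rel = rel, .reseed = FALSE)
    fs <- attr(accel, "sample_rate")
    f_true <- attr(accel, "true_tbf")
    swim <- attr(accel, "swimming")
    at <- accel$time
    per$true_tbf <- per$true_tbaa <- per$true_odba <- NA_real_
    for (i in seq_len(n_cycles)) {
      idx <- at >= rec_start[i] & at < rec_end[i]
      sw <- swim[idx]
      per$true_tbf[i] <- if (any(sw)) mean(f_true[idx][sw]) else NA_real_
      per$true_tbaa[i] <- config$tailbeat_amp_base * mean(sw)
      per$true_odba[i] <- (2 / pi) * 1.3 * config$tailbeat_amp_base * mean(sw)
    }
  }

  blank_pre_mid <- -1.5
  blank_post_mid <- duration_h + 1.5
  blanks <- list(
    pre = simulate_blank_run(config, at_time = blank_pre_mid,
                             duration_h = 3, .reseed = FALSE),
    post = simulate_blank_run(config, at_time = blank_post_mid,
                              duration_h = 3, .reseed = FALSE),
    mid_times_h = c(pre = blank_pre_mid, post = blank_post_mid)
  )

  truth <- list(
    per_period = per,
    true_mrmr = config$true_mrmr,
    true_mmr = config$true_mrmr * config$chase_boost,
    true_as = config$true_mrmr * (config$chase_boost - 1),
    true_ccrit = ccrit,
    true_scrit = ccrit / sat_conc,
    true_pcrit = ccrit / sat_conc * ambient_po2(cond),
    n_sub_ccrit_periods = sum(per$sub_ccrit),
    background = c(start = config$background_rate_start,
                   end = config$background_rate_end,
                   duration_h = duration_h)
  )

  structure(
    list(oxygen_trace = trace, accel_trace = accel, schedule = schedule,
         blanks = blanks, truth = truth, spec = spec, conditions = cond,
         config = config),
    class = "simulated_trial"
  )
}

#' Simulate a blank (no animal) oxygen run
#'
#' The tank declines at the whole-tank microbial background rate linearly
#' interpolated at `at_time` (trial hours; the trial spans `[0, duration]`,
#' blanks sit outside it), divided by the tank volume, plus sensor noise.
#'
#' @param config A [sim_config()].
#' @param at_time Trial time of the blank midpoint, hours.
#' @param duration_h Blank length in hours. Default 3.
#' @param .reseed Reset the RNG from `config$seed`? Default TRUE (standalone
#'   use); the trial simulator passes FALSE to keep one stream.
#' @return An [oxygen_trace()] with time in seconds from blank start.
#' @export
simulate_blank_run <- function(config, at_time, duration_h = 3,
                               .reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (duration_h <= 0) stop("blank duration must be positive")
  if (.reseed) set.seed(config$seed)
  cond <- sim_conditions(config)
  sat_conc <- o2_saturation_concentration(cond)
  total_h <- config$normoxia_hours +
    if (is.null(config$hypoxia_step_schedule)) 0
    else sum(config$hypoxia_step_schedule$hold_hours)
  rate <- sim_background(config, max(total_h, 1e-9))(at_time)  # mg O2/h tank
  n <- round(duration_h * 3600)
  tt <- 0:(n - 1L)
  o2 <- sat_conc - rate / config$respirometer_volume * tt / 3600
  o2 <- o2 + stats::rnorm(n, 0, config$sensor_noise_sd)
  o2[o2 < 0] <- 0
  oxygen_trace(tt, o2, config$temperature, conditions = cond)
}

#' Simulate a 25-Hz swimming acceleration signal
#'
#' The lateral (z) axis carries a tailbeat sinusoid whose frequency follows
#' the relative metabolic rate (`mo2_rel`, per-second values resampled to
#' 25 Hz) above the critical oxygen level and stays at the base frequency
#' below it; smaller in-phase components on x and y (20% and 10% of the z
#' amplitude) emulate body roll-over of the sway. Stop bouts zero the
#' dynamic component. Gravity projects onto the static components.
#'
#' @param config A [sim_config()].
#' @param duration Signal length in seconds.
#' @param mo2_rel Optional per-second relative metabolic rate vector driving
#'   the tailbeat frequency (1 = routine swimming).
#' @param .reseed As in [simulate_blank_run()].
#' @return An [accel_trace()] with attributes `true_tbf` (per-sample Hz) and
#'   `swimming` (logical per sample).
#' @export
simulate_accel_signal <- function(config, duration, mo2_rel = NULL,
                                  .reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (duration <= 0) stop("duration must be positive")
  if (.reseed) set.seed(config$seed)
  fs <- 25
  n <- round(duration * fs)
  t <- (0:(n - 1L)) / fs
  rel <- if (is.null(mo2_rel)) rep(1, n) else {
    idx <- pmin(floor(t) + 1L, length(mo2_rel))
    mo2_rel[idx]
  }
  f <- config$tailbeat_freq_base * pmin(pmax(rel, 0.4), 3)
  swimming <- rep(TRUE, n)
  sb <- config$stop_bouts
  if (!is.null(sb) && nrow(sb) > 0) {
    for (k in seq_len(nrow(sb))) {
      swimming[t >= sb$start[k] & t < sb$start[k] + sb$duration[k]] <- FALSE
    }
  }
  phase <- 2 * pi * cumsum(f) / fs
  a <- config$tailbeat_amp_base
  gate <- as.numeric(swimming)
  dyn_z <- a * sin(phase) * gate
  dyn_x <- 0.2 * a * sin(phase + 0.7) * gate
  dyn_y <- 0.1 * a * sin(phase + 1.3) * gate
  grav <- c(x = 0.10, y = 0.97, z = 0.15)
  out <- accel_trace(t,
                     ax = grav["x"] + dyn_x,
                     ay = grav["y"] + dyn_y,
                     az = grav["z"] + dyn_z,
                     sample_rate = fs)
  attr(out, "true_tbf") <- f
  attr(out, "swimming") <- swimming
  out
}
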