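#' Oxygen-logger trace
#'
#' A timestamped dissolved-oxygen series from the respirometer. Time is
#' seconds since trial start (end of the chase), nominally 1 Hz. If both
#' concentration and percent saturation are supplied they must agree through
#' the solubility function within 2%.
#'
#' @param time Seconds since trial start; strictly increasing.
#' @param o2_conc Dissolved oxygen, mg l-1 (non-negative).
#' @param temperature Water temperature, degrees C (scalar or per sample).
#' @param o2_sat Optional percent air saturation.
#' @param conditions Optional [gas_conditions()]; used to derive saturation
#'   from concentration (or check their agreement).
#' @return A data frame of class `oxygen_trace` with columns
#'   `time`, `o2_conc`, `o2_sat`, `temperature`.
#' @export
oxygen_trace <- function(time, o2_conc, temperature, o2_sat = NULL,
                         conditions = NULL) {
  stopifnot(length(time) == length(o2_conc))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(o2_conc < 0)) stop("o2_conc must be non-negative")
  if (length(temperature) == 1L) temperature <- rep(temperature, length(time))
  if (!is.null(conditions)) {
    sat_derived <- o2_conc_to_sat(o2_conc, conditions)
    if (!is.null(o2_sat)) {
      ref <- o2_sat_to_conc(o2_sat, conditions)
      ok <- ifelse(o2_conc > 0.1, abs(ref - o2_conc) / o2_conc <= 0.02, TRUE)
      if (!all(ok))
        stop("o2_conc and o2_sat disagree by more than 2% through the ",
             "solubility function")
    } else {
      o2_sat <- sat_derived
    }
  }
  if (is.null(o2_sat)) o2_sat <- rep(NA_real_, length(time))
  out <- data.frame(time = time, o2_conc = o2_conc, o2_sat = o2_sat,
                    temperature = temperature)
  class(out) <- c("oxygen_trace", "data.frame")
  out
}

#' Intermittent-flow trial schedule
#'
#' Ordered, non-overlapping flush/measure cycles. Each measurement period is
#' an equilibration interval (default 3 min, to let the tank mix) followed by
#' the recording span (default 12 min) over which the MO2 slope is fitted.
#'
#' @param cycles Data frame with columns `flush_start`, `flush_end`,
#'   `measure_start`, `measure_end` (seconds since trial start).
#' @param equilibration Equilibration interval, s. Default 180.
#' @param recording Recording span, s. Default 720.
#' @param chase_end_time Time of chase end, s. Default 0.
#' @return An object of class `trial_schedule`.
#' @export
trial_schedule <- function(cycles, equilibration = 180, recording = 720,
                           chase_end_time = 0) {
  need <- c("flush_start", "flush_end", "measure_start", "measure_end")
  stopifnot(all(need %in% names(cycles)))
  if (nrow(cycles) > 0) {
    if (any(cycles$measure_end - cycles$measure_start <
            equilibration + recording))
      stop("equilibration + recording must fit inside every measure window")
    ms <- cycles$measure_start
    if (is.unsorted(ms, strictly = TRUE))
      stop("cycles must be ordered by measure_start")
  }
  structure(
    list(cycles = cycles, equilibration = equilibration,
         recording = recording, chase_end_time = chase_end_time),
    class = "trial_schedule"
  )
}

#' Build a regular measure-first schedule
#'
#' Convenience constructor for the protocol where the respirometer is sealed
#' immediately after the chase (measurement first), then flushed, repeating.
#'
#' @param n_cycles Number of flush/measure cycles.
#' @param measure_minutes Length of the sealed measurement period. Default 15.
#' @param flush_minutes Length of the flushing period. Default 30.
#' @param equilibration,recording Seconds; see [trial_schedule()].
#' @param start Trial start time, s. Default 0.
#' @return A `trial_schedule`.
#' @export
regular_schedule <- function(n_cycles, measure_minutes = 15,
                             flush_minutes = 30, equilibration = 180,
                             recording = 720, start = 0) {
  cyc_len <- (measure_minutes + flush_minutes) * 60
  t0 <- start + (seq_len(n_cycles) - 1L) * cyc_len
  cycles <- data.frame(
    measure_start = t0,
    measure_end = t0 + measure_minutes * 60,
    flush_start = t0 + measure_minutes * 60,
    flush_end = t0 + cyc_len
  )
  trial_schedule(cycles, equilibration = equilibration,
                 recording = recording, chase_end_time = start)
}

#' Respirometer geometry and animal size
#'
#' The effective volume used in the MO2 calculation is the tank volume
#' corrected for the volume of the animal (assumed neutrally buoyant at
#' 1 l per kg body mass unless given).
#'
#' @param animal_mass Body mass, kg.
#' @param tank_volume Respirometer volume, litres. Default 1500.
#' @param animal_volume Animal volume, litres. Default `animal_mass` (1 l/kg).
#' @return An object of class `respirometer_spec`.
#' @export
respirometer_spec <- function(animal_mass, tank_volume = 1500,
                              animal_volume = animal_mass * 1.0) {
  stopifnot(animal_mass > 0, animal_volume >= 0)
  if (tank_volume <= animal_volume)
    stop("tank_volume must exceed animal_volume")
  structure(
    list(tank_volume = tank_volume, animal_mass = animal_mass,
         animal_volume = animal_volume,
         effective_volume = tank_volume - animal_volume),
    class = "respirometer_spec"
  )
}

#' Cut an oxygen trace into recording windows
#'
#' One window per cycle, covering exactly the post-equilibration recording
#' span `[measure_start + equilibration, measure_start + equilibration +
#' recording)`. Windows with fewer than 2 samples are dropped with a warning.
#'
#' @param trace An [oxygen_trace()].
#' @param schedule A [trial_schedule()].
#' @return A list of `oxygen_trace` subsets, each with attributes
#'   `period_index`, `rec_start`, `rec_end`.
#' @export
segment_trial <- function(trace, schedule) {
  stopifnot(inherits(trace, "oxygen_trace"),
            inherits(schedule, "trial_schedule"))
  cycles <- schedule$cycles
  out <- list()
  for (i in seq_len(nrow(cycles))) {
    rs <- cycles$measure_start[i] + schedule$equilibration
    re <- rs + schedule$recording
    idx <- trace$time >= rs & trace$time < re
    win <- trace[idx, , drop = FALSE]
    if (nrow(win) < 2L) {
      warning(sprintf("recording window %d has fewer than 2 samples; dropped", i))
      next
    }
    attr(win, "period_index") <- i
    attr(win, "rec_start") <- rs
    attr(win, "rec_end") <- re
    class(win) <- c("oxygen_trace", "data.frame")
    out[[length(out) + 1L]] <- win
  }
  out
}

#' Fit one metabolic-rate measurement from a recording window
#'
#' Ordinary least-squares slope `b` (mg l-1 s-1) of oxygen concentration on
#' time over the recording window, converted to a mass-specific rate:
#' `MO2 = (-b) x 3600 x (tank_volume - animal_volume) / animal_mass`
#' in mg O2 kg-1 h-1 (positive for declining oxygen). Records with regression
#' R2 below `r2_min` are retained but flagged `qc_pass = FALSE`; a
#' zero-variance (flat) trace has R2 defined as 0. The normoxic/hypoxic phase
#' is assigned by mean saturation (`>= normoxia_sat` percent is normoxic).
#'
#' @param window One element of [segment_trial()] output.
#' @param spec A [respirometer_spec()].
#' @param conditions Optional [gas_conditions()] used to fill `mean_o2_sat`
#'   when the trace lacks a saturation column.
#' @param r2_min QC threshold on R2. Default 0.8.
#' @param normoxia_sat Phase boundary in percent saturation. Default 80.
#' @return One-row data frame: `period_index`, `mid_time`, `slope_b`,
#'   `r_squared`, `mo2`, `mean_o2_sat`, `mean_o2_conc`, `n_samples`, `phase`,
#'   `qc_pass`, `background_corrected`.
#' @export
fit_period_mo2 <- function(window, spec, conditions = NULL, r2_min = 0.8,
                           normoxia_sat = 80) {
  stopifnot(inherits(spec, "respirometer_spec"))
  if (nrow(window) < 2L) stop("window must contain at least 2 samples")
  if (stats::var(window$time) == 0) stop("constant time vector")
  fit <- ols_fit(window$time, window$o2_conc)
  mo2 <- (-fit$slope) * 3600 * spec$effective_volume / spec$animal_mass
  mean_conc <- mean(window$o2_conc)
  mean_sat <- if (all(is.na(window$o2_sat)) && !is.null(conditions)) {
    o2_conc_to_sat(mean_conc, conditions)
  } else {
    mean(window$o2_sat)
  }
  data.frame(
    period_index = attr(window, "period_index") %||% NA_integer_,
    mid_time = mean(range(window$time)),
    slope_b = fit$slope,
    r_squared = fit$r_squared,
    mo2 = mo2,
    mean_o2_sat = mean_sat,
    mean_o2_conc = mean_conc,
    n_samples = nrow(window),
    phase = if (!is.na(mean_sat) && mean_sat >= normoxia_sat) "normoxic"
            else "hypoxic",
    qc_pass = fit$r_squared >= r2_min,
    background_corrected = FALSE
  )
}

#' Fit all recording windows of a trial
#'
#' @inheritParams segment_trial
#' @inheritParams fit_period_mo2
#' @return Data frame of MO2 records, one row per surviving window.
#' @export
fit_mo2_records <- function(trace, schedule, spec, conditions = NULL,
                            r2_min = 0.8, normoxia_sat = 80) {
  windows <- segment_trial(trace, schedule)
  if (length(windows) == 0L)
    return(fit_period_mo2_empty())
  do.call(rbind, lapply(windows, fit_period_mo2, spec = spec,
                        conditions = conditions, r2_min = r2_min,
                        normoxia_sat = normoxia_sat))
}

fit_period_mo2_empty <- function() {
  data.frame(period_index = integer(), mid_time = numeric(),
             slope_b = numeric(), r_squared = numeric(), mo2 = numeric(),
             mean_o2_sat = numeric(), mean_o2_conc = numeric(),
             n_samples = integer(), phase = character(),
             qc_pass = logical(), background_corrected = logical())
}

#' Whole-tank oxygen decline rate of a blank run
#'
#' Fits the oxygen slope of a blank (no animal) trace and converts it to a
#' whole-tank rate in mg O2 h-1. The blank uses the full tank volume.
#'
#' @param trace An [oxygen_trace()] recorded without the animal.
#' @param tank_volume Respirometer volume in litres. Default 1500.
#' @param time_h Time to attach to the rate (hours relative to trial start);
#'   defaults to the trace midpoint.
#' @return One-row data frame with `time` (h) and `tank_rate` (mg O2 h-1).
#' @export
fit_blank_rate <- function(trace, tank_volume = 1500, time_h = NULL) {
  fit <- ols_fit(trace$time, trace$o2_conc)
  rate <- (-fit$slope) * 3600 * tank_volume
  if (rate < 0)
    warning("negative blank respiration rate (oxygen increased during blank)")
  data.frame(time = time_h %||% (mean(range(trace$time)) / 3600),
             tank_rate = rate)
}

#' Linear background (microbial) respiration model
#'
#' Fits a straight line through pre- and post-trial blank rates, giving the
#' whole-tank microbial oxygen consumption (mg O2 h-1) as a function of trial
#' time. With a single blank the function is constant (with a warning); with
#' none it is zero (with a warning).
#'
#' @param blank_rates Data frame with columns `time` (h) and `tank_rate`
#'   (mg O2 h-1), e.g. rbind of [fit_blank_rate()] rows.
#' @return A function of time in hours returning mg O2 h-1, with attribute
#'   `coefficients` (intercept, slope per hour).
#' @export
estimate_background <- function(blank_rates) {
  if (is.null(blank_rates) || nrow(blank_rates) == 0L) {
    warning("no blank runs supplied; assuming zero background respiration")
    f <- function(t) rep(0, length(t))
    attr(f, "coefficients") <- c(intercept = 0, slope = 0)
    return(f)
  }
  if (nrow(blank_rates) == 1L) {
    warning("single blank run; background treated as constant over the trial")
    k <- blank_rates$tank_rate[1]
    f <- function(t) rep(k, length(t))
    attr(f, "coefficients") <- c(intercept = k, slope = 0)
    return(f)
  }
  fit <- ols_fit(blank_rates$time, blank_rates$tank_rate)
  f <- function(t) fit$intercept + fit$slope * t
  attr(f, "coefficients") <- c(intercept = fit$intercept, slope = fit$slope)
  f
}

#' Subtract background respiration from MO2 records
#'
#' The background is a whole-tank rate; it is removed at the tank level
#' before mass normalisation, i.e. each record's `mo2` is reduced by
#' `background(mid_time in hours) / animal_mass`.
#'
#' @param records Output of [fit_mo2_records()], uncorrected.
#' @param background Function from [estimate_background()].
#' @param spec A [respirometer_spec()].
#' @return The records with `mo2` corrected and `background_corrected = TRUE`.
#' @export
apply_background_correction <- function(records, background, spec) {
  stopifnot(inherits(spec, "respirometer_spec"))
  if (nrow(records) > 0 && any(records$background_corrected))
    stop("records are already background-corrected")
  bg <- background(records$mid_time / 3600)
  records$mo2 <- records$mo2 - bg / spec$animal_mass
  records$background_corrected <- TRUE
  records
}
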