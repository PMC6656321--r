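#' Read an oxygen-logger CSV
#'
#' Tolerant reader for 1-Hz oxygen logs. The column map names which CSV
#' columns hold time (s), oxygen (mg l-1 and/or percent saturation) and
#' temperature; when only saturation is present, concentration is derived
#' through the solubility function (and vice versa) if `conditions` is given.
#'
#' @param path CSV path.
#' @param col_map Named list mapping `time`, `o2_conc`, `o2_sat`,
#'   `temperature` to CSV column names (entries may be omitted).
#' @param conditions Optional [gas_conditions()].
#' @return An [oxygen_trace()].
#' @export
read_oxygen_csv <- function(path,
                            col_map = list(time = "time_s",
                                           o2_conc = "o2_mg_l",
                                           o2_sat = "o2_sat_pct",
                                           temperature = "temp_c"),
                            conditions = NULL) {
  d <- utils::read.csv(path)
  pick <- function(key) {
    nm <- col_map[[key]]
    if (is.null(nm) || !nm %in% names(d)) NULL else d[[nm]]
  }
  o2_conc <- pick("o2_conc")
  o2_sat <- pick("o2_sat")
  if (is.null(o2_conc)) {
    if (is.null(o2_sat) || is.null(conditions))
      stop("need an o2_conc column, or o2_sat plus gas conditions")
    o2_conc <- o2_sat_to_conc(o2_sat, conditions)
  }
  temp <- pick("temperature")
  if (is.null(temp)) {
    if (is.null(conditions)) stop("need a temperature column or conditions")
    temp <- conditions$temperature
  }
  oxygen_trace(pick("time"), o2_conc, temp, o2_sat = o2_sat,
               conditions = conditions)
}

#' Write an oxygen trace as CSV
#' @param trace An [oxygen_trace()].
#' @param path Output path.
#' @export
write_oxygen_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$time, o2_mg_l = trace$o2_conc,
               o2_sat_pct = trace$o2_sat, temp_c = trace$temperature),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an accelerometer CSV
#'
#' @param path CSV path.
#' @param col_map Named list mapping `time`, `ax`, `ay`, `az` to CSV columns;
#'   if `time` is absent, sample index at `sample_rate` is used.
#' @param sample_rate Hz. Default 25.
#' @param units `"g"` (default) or `"ms2"` (converted with g = 9.80665).
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path,
                           col_map = list(time = "time_s", ax = "ax_g",
                                          ay = "ay_g", az = "az_g"),
                           sample_rate = 25, units = c("g", "ms2")) {
  units <- match.arg(units)
  d <- utils::read.csv(path)
  k <- if (units == "ms2") 1 / 9.80665 else 1
  tm <- if (!is.null(col_map$time) && col_map$time %in% names(d))
    d[[col_map$time]] else (seq_len(nrow(d)) - 1L) / sample_rate
  accel_trace(tm, d[[col_map$ax]] * k, d[[col_map$ay]] * k,
              d[[col_map$az]] * k, sample_rate = sample_rate)
}

#' Write an acceleration trace as CSV
#' @param trace An [accel_trace()].
#' @param path Output path.
#' @export
write_accel_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$time, ax_g = trace$ax, ay_g = trace$ay,
               az_g = trace$az),
    path, row.names = FALSE)
  invisible(path)
}

#' Read/write a trial schedule as CSV
#'
#' The CSV holds one row per cycle (`flush_start`, `flush_end`,
#' `measure_start`, `measure_end`, seconds) plus `equilibration`,
#' `recording` and `chase_end_time` columns repeated on each row.
#'
#' @param path CSV path.
#' @return A [trial_schedule()].
#' @export
read_schedule_csv <- function(path) {
  d <- utils::read.csv(path)
  trial_schedule(
    d[, c("flush_start", "flush_end", "measure_start", "measure_end")],
    equilibration = d$equilibration[1], recording = d$recording[1],
    chase_end_time = d$chase_end_time[1])
}

#' @rdname read_schedule_csv
#' @param schedule A [trial_schedule()].
#' @export
write_schedule_csv <- function(schedule, path) {
  d <- schedule$cycles
  d$equilibration <- schedule$equilibration
  d$recording <- schedule$recording
  d$chase_end_time <- schedule$chase_end_time
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated trial to disk as the CSV/JSON bundle the pipeline reads
#'
#' @param trial A `simulated_trial`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trial_bundle <- function(trial, dir) {
  stopifnot(inherits(trial, "simulated_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_oxygen_csv(trial$oxygen_trace, file.path(dir, "oxygen.csv"))
  if (!is.null(trial$accel_trace))
    write_accel_csv(trial$accel_trace, file.path(dir, "accel.csv"))
  write_oxygen_csv(trial$blanks$pre, file.path(dir, "blank_pre.csv"))
  write_oxygen_csv(trial$blanks$post, file.path(dir, "blank_post.csv"))
  write_schedule_csv(trial$schedule, file.path(dir, "schedule.csv"))
  truth <- trial$truth
  jsonlite::write_json(
    list(per_period = truth$per_period,
         scalars = truth[setdiff(names(truth), "per_period")],
         blank_mid_times_h = as.list(trial$blanks$mid_times_h)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- trial$config
  cfg$hypoxia_step_schedule <- if (is.null(cfg$hypoxia_step_schedule)) NULL
    else as.list(cfg$hypoxia_step_schedule)
  cfg$stop_bouts <- if (is.null(cfg$stop_bouts)) NULL
    else as.list(cfg$stop_bouts)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
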