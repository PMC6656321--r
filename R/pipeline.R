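#' Run the full analysis pipeline on a trial bundle
#'
#' Orchestrates respirometry (segmentation, slope fits, QC, background
#' correction), metabolic metrics (MMR, mRMR, aerobic scope, critical
#' oxygen), and — when an acceleration file is present — the activity
#' metrics and the aligned per-period table. Writes per-stage CSV/JSON
#' outputs plus a run log carrying the package version, a config hash and
#' the seed, and returns the report invisibly-printable list.
#'
#' @param config Either a path to a YAML run-config or a list with entries:
#'   `oxygen_csv`, `schedule_csv`, optional `accel_csv`, optional
#'   `blank_pre_csv`/`blank_post_csv`, optional `blank_mid_times_h`
#'   (pre/post hours), `animal_mass`, optional `tank_volume` (1500),
#'   `temperature`, optional `salinity` (35), `barometric_pressure` (760),
#'   optional thresholds `r2_min` (0.8), `normoxia_sat` (80), `quantile`
#'   (0.10), optional `animal_id`, `total_length`, `seed`, and `output_dir`.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  needed <- c("oxygen_csv", "schedule_csv", "animal_mass", "temperature",
              "output_dir")
  missing <- setdiff(needed, names(config))
  if (length(missing) > 0)
    stop("run config is missing fields: ", paste(missing, collapse = ", "))
  r2_min <- config$r2_min %||% 0.8
  normoxia_sat <- config$normoxia_sat %||% 80
  quantile <- config$quantile %||% 0.10
  cond <- gas_conditions(config$temperature, config$salinity %||% 35,
                         config$barometric_pressure %||% 760)
  spec <- respirometer_spec(config$animal_mass,
                            tank_volume = config$tank_volume %||% 1500)
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  hash <- config_hash(config)
  log_line("ramresp %s | config %s | seed %s",
           as.character(utils::packageVersion("ramresp")), hash,
           config$seed %||% "none")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  trace <- stage("read_oxygen", read_oxygen_csv(config$oxygen_csv,
                                                conditions = cond))
  schedule <- stage("read_schedule", read_schedule_csv(config$schedule_csv))
  records <- stage("respirometry",
                   fit_mo2_records(trace, schedule, spec, cond,
                                   r2_min = r2_min,
                                   normoxia_sat = normoxia_sat))
  log_line("respirometry: %d records, %d pass QC", nrow(records),
           sum(records$qc_pass))

  blanks <- NULL
  if (!is.null(config$blank_pre_csv) || !is.null(config$blank_post_csv)) {
    mids <- config$blank_mid_times_h %||% list()
    rows <- list()
    if (!is.null(config$blank_pre_csv))
      rows$pre <- fit_blank_rate(read_oxygen_csv(config$blank_pre_csv,
                                                 conditions = cond),
                                 tank_volume = spec$tank_volume,
                                 time_h = mids$pre %||% NULL)
    if (!is.null(config$blank_post_csv))
      rows$post <- fit_blank_rate(read_oxygen_csv(config$blank_post_csv,
                                                  conditions = cond),
                                  tank_volume = spec$tank_volume,
                                  time_h = mids$post %||% NULL)
    blanks <- do.call(rbind, rows)
  }
  background <- stage("background", suppressWarnings(estimate_background(blanks)))
  records <- stage("background",
                   apply_background_correction(records, background, spec))

  qc <- records[records$qc_pass, , drop = FALSE]
  norm <- qc[qc$phase == "normoxic", , drop = FALSE]
  hyp <- qc[qc$phase == "hypoxic", , drop = FALSE]
  summ <- stage("oxy_metrics", metabolic_summary(norm, quantile))
  crit <- stage("oxy_metrics",
                if (nrow(hyp) >= 2)
                  detect_crit(hyp, summ$mrmr, cond)
                else crit_not_found(summ$mrmr, "fewer than 2 hypoxic records"))

  activity <- NULL
  if (!is.null(config$accel_csv)) {
    if (file.exists(config$accel_csv)) {
      accel <- stage("biologging", read_accel_csv(config$accel_csv))
      activity <- stage("biologging", activity_by_period(accel, schedule))
    } else {
      warning("acceleration file missing; producing a respirometry-only report")
      log_line("biologging: accel file missing, skipped")
    }
  }
  aligned <- stage("align",
                   align_records(records, activity, crit,
                                 animal_id = config$animal_id %||% "A1",
                                 temperature = config$temperature,
                                 total_length = config$total_length %||% NA))

  utils::write.csv(records, file.path(outdir, "mo2_records.csv"),
                   row.names = FALSE)
  utils::write.csv(aligned, file.path(outdir, "aligned_records.csv"),
                   row.names = FALSE)
  if (!is.null(activity))
    utils::write.csv(activity, file.path(outdir, "period_activity.csv"),
                     row.names = FALSE)

  report <- list(
    version = as.character(utils::packageVersion("ramresp")),
    config_hash = hash,
    seed = config$seed %||% NULL,
    n_records = nrow(records),
    n_qc_pass = sum(records$qc_pass),
    metabolic_summary = as.list(summ),
    crit_oxygen = list(
      found = crit$found,
      ccrit = if (crit$found) crit$ccrit else NULL,
      scrit_pct = if (crit$found) 100 * crit$scrit else NULL,
      pcrit = if (crit$found) crit$pcrit else NULL,
      n_points = crit$n_points),
    background = as.list(attr(background, "coefficients")),
    activity_present = !is.null(activity)
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("pipeline complete: mmr %.1f mrmr %.1f as %.1f ccrit %s",
           summ$mmr, summ$mrmr, summ$aerobic_scope,
           if (crit$found) sprintf("%.2f", crit$ccrit) else "not found")
  class(report) <- "pipeline_report"
  report
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

#' Simulate a trial and write its file bundle plus a matching run config
#'
#' Wraps [simulate_shark_trial()] and [write_trial_bundle()], and writes a
#' `run_config.yaml` that [run_pipeline()] can consume directly.
#'
#' @param config A [sim_config()] (or a path to a YAML of its fields).
#' @param dir Output directory.
#' @return Path to the written run config, invisibly.
#' @export
simulate_to_files <- function(config, dir) {
  if (is.character(config)) config <- do.call(sim_config, read_sim_yaml(config))
  trial <- simulate_shark_trial(config)
  write_trial_bundle(trial, dir)
  run_cfg <- list(
    oxygen_csv = file.path(dir, "oxygen.csv"),
    schedule_csv = file.path(dir, "schedule.csv"),
    accel_csv = if (!is.null(trial$accel_trace))
      file.path(dir, "accel.csv") else NULL,
    blank_pre_csv = file.path(dir, "blank_pre.csv"),
    blank_post_csv = file.path(dir, "blank_post.csv"),
    blank_mid_times_h = as.list(trial$blanks$mid_times_h),
    animal_mass = config$animal_mass,
    tank_volume = config$respirometer_volume,
    temperature = config$temperature,
    salinity = config$salinity,
    barometric_pressure = config$barometric_pressure,
    animal_id = "SIM",
    total_length = config$animal_length,
    seed = config$seed,
    output_dir = file.path(dir, "out"))
  path <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(run_cfg, path)
  invisible(path)
}

read_sim_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$hypoxia_step_schedule))
    raw$hypoxia_step_schedule <- as.data.frame(raw$hypoxia_step_schedule)
  if (!is.null(raw$stop_bouts))
    raw$stop_bouts <- as.data.frame(raw$stop_bouts)
  raw
}

#' Validate a pipeline report against the shipped schema
#'
#' Structural check of required fields and types against the JSON schema in
#' `inst/extdata/report-schema.json`.
#'
#' @param report A `pipeline_report` or a path to a report JSON.
#' @return TRUE invisibly, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "ramresp"))
  for (f in unlist(schema$required)) {
    if (!f %in% names(report)) stop("report missing required field: ", f)
  }
  for (f in unlist(schema$properties$metabolic_summary$required)) {
    if (!f %in% names(report$metabolic_summary) ||
        !is.numeric(report$metabolic_summary[[f]]))
      stop("metabolic_summary missing numeric field: ", f)
  }
  if (!is.logical(report$crit_oxygen$found %||% NA))
    stop("crit_oxygen.found must be boolean")
  invisible(TRUE)
}

#' Load the packaged animal-cohort fixture
#'
#' Size and treatment summary of the 13 juvenile sandbar sharks (animal id,
#' year, mass, total length, treatment temperatures, accelerometer fitted).
#'
#' @return Data frame with a list-column-free layout; `treatments` is a
#'   semicolon-separated string of temperatures.
#' @export
load_animal_fixture <- function() {
  d <- utils::read.csv(system.file("extdata", "table1.csv",
                                   package = "ramresp"))
  stopifnot(nrow(d) == 13L)
  d
}

#' Summary statistics of the packaged cohort
#'
#' @param tag_mass_g Accelerometer mass in grams (for the relative-mass
#'   range of tagged animals). Default 27.
#' @return List: `n_animals`, `n_all_three_treatments`, `mass_range_kg`,
#'   `tl_range_cm`, `per_treatment` (animals per temperature),
#'   `accel_rel_mass_pct` (range of tag mass as percent body mass among
#'   tagged animals, 2 significant digits).
#' @export
fixture_stats <- function(tag_mass_g = 27) {
  d <- load_animal_fixture()
  tr <- strsplit(d$treatments, ";")
  temps <- sort(unique(as.numeric(unlist(tr))))
  per <- vapply(temps, function(tp)
    sum(vapply(tr, function(x) tp %in% as.numeric(x), logical(1))),
    numeric(1))
  names(per) <- temps
  tagged <- d[d$accelerometer, ]
  rel <- tag_mass_g / (tagged$mass_kg * 1000) * 100
  list(
    n_animals = nrow(d),
    n_all_three_treatments = sum(lengths(tr) == 3L),
    mass_range_kg = range(d$mass_kg),
    tl_range_cm = range(d$total_length_cm),
    per_treatment = per,
    accel_rel_mass_pct = signif(range(rel), 2)
  )
}
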