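# shared fixtures: all synthetic, built in code

# short protocol used where full 20-h normoxia is not needed
short_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    normoxia_hours = 6,
    hypoxia_step_schedule = data.frame(
      target_sat = c(70, 60, 48, 40, 32),
      hold_hours = 1),
    accelerometer = FALSE,
    ...)
}

# run respirometry + metrics on a simulated trial, returning summary + crit
recover_trial <- function(trial, quantile = 0.10) {
  recs <- fit_mo2_records(trial$oxygen_trace, trial$schedule, trial$spec,
                          trial$conditions)
  blanks <- rbind(
    fit_blank_rate(trial$blanks$pre,
                   tank_volume = trial$spec$tank_volume,
                   time_h = trial$blanks$mid_times_h["pre"]),
    fit_blank_rate(trial$blanks$post,
                   tank_volume = trial$spec$tank_volume,
                   time_h = trial$blanks$mid_times_h["post"]))
  bg <- estimate_background(blanks)
  recs <- apply_background_correction(recs, bg, trial$spec)
  qc <- recs[recs$qc_pass, , drop = FALSE]
  summ <- metabolic_summary(qc[qc$phase == "normoxic", , drop = FALSE],
                            quantile)
  hyp <- qc[qc$phase == "hypoxic", , drop = FALSE]
  crit <- if (nrow(hyp) >= 2)
    detect_crit(hyp, summ$mrmr, trial$conditions)
  else NULL
  list(records = recs, summary = summ, crit = crit)
}

# grouped synthetic activity-metabolism data for the inference tests
make_aligned <- function(seed = 1, n_anim = 6, n_per = 12, b0 = 100,
                         b_tbf = 50, b_odba = 0, b_tbaa = 0, b_tl = 0,
                         sd_anim = 10, sd_res = 5) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_anim), function(a) {
    u <- stats::rnorm(1, 0, sd_anim)
    tl <- stats::rnorm(1, 95, 8)
    tbf <- stats::runif(n_per, 0.8, 1.6)
    odba <- stats::runif(n_per, 0.1, 0.5)
    tbaa <- stats::runif(n_per, 0.2, 0.4)
    data.frame(
      animal_id = paste0("A", a), period_index = seq_len(n_per),
      temperature = 28, tbf = tbf, odba = odba, tbaa = tbaa,
      total_length = tl,
      mo2 = b0 + b_tbf * tbf + b_odba * odba + b_tbaa * tbaa + b_tl * tl +
        u + stats::rnorm(n_per, 0, sd_res))
  }))
}

# brute-force oracle for the critical-oxygen suffix rule: scan every start
# index, keep the first whose whole tail lies below mrmr, then regress
brute_force_crit <- function(records, mrmr) {
  n <- nrow(records)
  start <- NA_integer_
  for (i in seq_len(n)) {
    if (all(records$mo2[i:n] < mrmr)) { start <- i; break }
  }
  if (is.na(start) || n - start + 1L < 2L) return(NULL)
  idx <- start:n
  x <- records$mean_o2_conc[idx]; y <- records$mo2[idx]
  if (stats::var(x) == 0) return(NULL)
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[2]
  if (slope <= 0) return(NULL)
  list(start = start, ccrit = (mrmr - stats::coef(fit)[1]) / slope)
}
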