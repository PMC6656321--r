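test_that("crash assignment partitions hypoxic records at first attainment", {
  rec <- data.frame(mean_o2_conc = c(5, 4, 3.6, 2.5, 2))
  expect_identical(assign_crash(rec, ccrit = 3.25), c(1L, 1L, 1L, 0L, 0L))
  # all above the critical level: never reached
  expect_identical(assign_crash(rec, ccrit = 1.5), rep(1L, 5))
  # reached immediately
  expect_identical(assign_crash(rec, ccrit = 6), rep(0L, 5))
  expect_identical(assign_crash(rec[0, , drop = FALSE], 3), integer())
})

test_that("alignment joins records, activity and crash bookkeeping", {
  mo2 <- data.frame(
    period_index = 1:6, mid_time = (1:6) * 2700 + 540,
    slope_b = -1e-4, r_squared = c(0.99, 0.99, 0.5, 0.99, 0.99, 0.99),
    mo2 = c(200, 190, 180, 160, 120, 100),
    mean_o2_sat = c(95, 92, 85, 70, 50, 35),
    mean_o2_conc = c(6.1, 5.9, 5.5, 4.5, 3.2, 2.2),
    n_samples = 720,
    phase = c("normoxic", "normoxic", "normoxic", "hypoxic", "hypoxic",
              "hypoxic"),
    qc_pass = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    background_corrected = TRUE)
  act <- data.frame(period_index = c(1, 2, 4, 5, 6),
                    mean_tbf = c(1.1, 1.0, 1.2, 0.9, NA),
                    mean_tbaa = c(0.3, 0.3, 0.35, 0.2, 0.05),
                    mean_odba = c(0.4, 0.38, 0.45, 0.3, 0.1),
                    stop_fraction = c(0, 0, 0, 0.2, 1))
  crit <- detect_crit(
    data.frame(mo2 = c(160, 120, 100), mean_o2_conc = c(4.5, 3.2, 2.2)),
    mrmr = 150, gas_conditions(28))
  al <- align_records(mo2, act, crit, animal_id = "SB33", temperature = 28,
                      total_length = 109)
  # QC-failing record dropped; activity joined by period
  expect_equal(nrow(al), 5)
  expect_false(3 %in% al$period_index)
  expect_equal(al$tbf[al$period_index == 4], 1.2)
  # normoxic rows have no crash value; hypoxic rows partition around ccrit
  expect_true(all(is.na(al$crash[al$phase == "normoxic"])))
  hyp <- al[al$phase == "hypoxic", ]
  expect_identical(hyp$crash, assign_crash(hyp, crit$ccrit))
  expect_true(all(diff(hyp$crash) <= 0))
  # duplicate period indices refuse to join
  expect_error(align_records(rbind(mo2, mo2[1, ]), act, crit), "duplicate")
  # missing activity -> row kept with NA activity
  al2 <- align_records(mo2, act[act$period_index != 4, ], crit)
  expect_true(is.na(al2$tbf[al2$period_index == 4]))
})

test_that("exact linear data are recovered exactly and errors are raised", {
  d <- make_aligned(seed = 1, sd_anim = 0, sd_res = 0, b_tbf = 50)
  f <- fit_model(d, "tbf")
  expect_true(f$converged)
  est <- f$coefficients$estimate
  expect_equal(est[f$coefficients$term == "(Intercept)"], 100,
               tolerance = 1e-6)
  expect_equal(est[f$coefficients$term == "tbf"], 50, tolerance = 1e-6)
  # single animal cannot separate animal from residual variation
  d1 <- d[d$animal_id == "A1", ]
  expect_error(fit_model(d1, "tbf"), "2 animals")
  d8 <- d[d$animal_id %in% c("A1", "A2") & d$period_index <= 4, ]
  expect_error(fit_model(d8, "tbf"), "10 rows")
})

test_that("noisy interaction structure is recovered within its standard errors", {
  set.seed(21)
  slopes <- c("24" = 63, "28" = 142, "32" = -20)
  d <- do.call(rbind, lapply(1:6, function(a) {
    u <- stats::rnorm(1, 0, 5)
    do.call(rbind, lapply(c(24, 28, 32), function(tp) {
      tbf <- stats::runif(10, 0.8, 1.6)
      data.frame(animal_id = paste0("A", a), temperature = tp,
                 period_index = 1:10, tbf = tbf,
                 mo2 = 100 + slopes[as.character(tp)] * tbf + u +
                   stats::rnorm(10, 0, 4))
    }))
  }))
  d$temp_f <- factor(d$temperature)
  f <- fit_model(d, c("temp_f", "tbf"), interactions = "tbf:temp_f",
                 ar1 = FALSE)
  expect_true(f$converged)
  co <- f$coefficients
  b_tbf <- co$estimate[co$term == "tbf"]
  se_tbf <- co$std.error[co$term == "tbf"]
  expect_lt(abs(b_tbf - 63), 3 * se_tbf)
  is28 <- grepl("28", co$term) & grepl("tbf", co$term)
  is32 <- grepl("32", co$term) & grepl("tbf", co$term)
  b28 <- b_tbf + co$estimate[is28]
  b32 <- b_tbf + co$estimate[is32]
  expect_equal(b28, 142, tolerance = 0.1 * 142)
  expect_lt(b32, 10)  # negative generating slope recovered as ~ -20
})

test_that("BIC selection prefers truth, breaks ties toward parsimony", {
  d <- make_aligned(seed = 2, b_tbf = 50, b_odba = 60, sd_res = 3)
  cands <- list(
    list(covariates = "tbf"),
    list(covariates = c("tbf", "odba")),
    list(covariates = c("tbf", "odba", "tbaa")),
    list(covariates = c("tbf", "odba", "tbaa", "total_length")))
  sel <- select_by_bic(d, cands, ar1 = FALSE)
  expect_equal(sel$chosen, 2)
  expect_equal(sel$table$candidate[1], 2)
  # a duplicated spec ties exactly; the earlier one wins
  sel2 <- select_by_bic(d, list(list(covariates = c("tbf", "odba")),
                                list(covariates = c("tbf", "odba"))),
                        ar1 = FALSE)
  expect_equal(sel2$chosen, 1)
  # an always-zero covariate only costs parameters; simpler model wins
  d$zero <- 0 * d$tbf
  sel3 <- select_by_bic(d, list(list(covariates = c("tbf", "odba")),
                                list(covariates = c("tbf", "odba", "tbaa"))),
                        ar1 = FALSE)
  expect_equal(sel3$chosen, 1)
})

test_that("BIC ordering is invariant to affine covariate rescaling", {
  d <- make_aligned(seed = 3, b_tbf = 40, b_odba = 50, sd_res = 4)
  cands <- list(list(covariates = "tbf"),
                list(covariates = c("tbf", "odba")),
                list(covariates = "odba"))
  sel_a <- select_by_bic(d, cands, ar1 = FALSE)
  d2 <- d
  d2$tbf <- 10 * d2$tbf - 3
  d2$odba <- 0.1 * d2$odba + 1
  sel_b <- select_by_bic(d2, cands, ar1 = FALSE)
  expect_equal(sel_a$table$candidate, sel_b$table$candidate)
  expect_equal(sel_a$table$bic, sel_b$table$bic, tolerance = 1e-4)
})

test_that("cluster bootstrap is deterministic and never mixes animals", {
  d <- make_aligned(seed = 4)
  g <- data.frame(tbf = 1.2)
  b1 <- bootstrap_predictions(d, "tbf", grid = g, n_boot = 120, seed = 9,
                              ar1 = FALSE)
  b2 <- bootstrap_predictions(d, "tbf", grid = g, n_boot = 120, seed = 9,
                              ar1 = FALSE)
  expect_identical(b1$grid, b2$grid)
  expect_warning(bootstrap_predictions(d, "tbf", grid = g, n_boot = 50,
                                       seed = 1, ar1 = FALSE), "unstable")
  # two animals with distinct constant responses: every bootstrap
  # prediction must be a mean over whole animals, i.e. in {100, 150, 200}
  dd <- data.frame(animal_id = rep(c("A1", "A2"), each = 6),
                   period_index = rep(1:6, 2), temperature = 28,
                   tbf = 1, mo2 = rep(c(100, 200), each = 6))
  bb <- bootstrap_predictions(dd, character(0), grid = data.frame(x = 1),
                              n_boot = 120, seed = 2, ar1 = FALSE)
  preds <- stats::na.omit(as.vector(bb$predictions))
  expect_true(all(sapply(preds, function(p)
    min(abs(p - c(100, 150, 200))) < 1e-6)))
  # zero-noise data give degenerate intervals
  d0 <- make_aligned(seed = 5, sd_anim = 0, sd_res = 0)
  b0 <- bootstrap_predictions(d0, "tbf", grid = g, n_boot = 120, seed = 3,
                              ar1 = FALSE)
  expect_lt(b0$grid$upr - b0$grid$lwr, 1e-6)
})

test_that("temperature contrasts detect a Q10 = 2 warming effect and bookkeeping holds", {
  set.seed(31)
  q10 <- function(t) 150 * 2^((t - 24) / 10)
  mk <- function(n_anim, drop32 = character()) {
    do.call(rbind, lapply(seq_len(n_anim), function(a) {
      id <- paste0("S", a)
      temps <- c(24, 28, 32)
      if (id %in% drop32) temps <- c(24, 28)
      u <- stats::rnorm(1, 0, 8)
      data.frame(animal_id = id, temperature = temps,
                 mrmr = q10(temps) + u + stats::rnorm(length(temps), 0, 6),
                 mmr = 2 * q10(temps) + u + stats::rnorm(length(temps), 0, 12))
    }))
  }
  d <- mk(12)
  d$aerobic_scope <- d$mmr - d$mrmr
  ctr <- temperature_contrasts(d, metrics = c("mrmr", "mmr"))
  c2432 <- ctr[ctr$metric == "mrmr" & ctr$pair == "32-24", ]
  expect_gt(c2432$estimate, 0)
  expect_lt(c2432$p_value, 0.05)
  expect_true(c2432$lower < c2432$estimate & c2432$estimate < c2432$upper)
  # identical values across temperatures -> all estimates ~ 0
  d0 <- mk(6); d0$mrmr <- 150
  ctr0 <- temperature_contrasts(d0, metrics = "mrmr")
  expect_equal(ctr0$estimate, rep(0, 3), tolerance = 1e-6)
  # an animal missing 32 C still contributes to the 24x28 pair
  dm <- mk(8, drop32 = "S1")
  ctrm <- temperature_contrasts(dm, metrics = "mrmr")
  expect_equal(nrow(ctrm), 3)
  expect_true(all(is.finite(ctrm$estimate)))
})
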