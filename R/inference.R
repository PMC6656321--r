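#' Assign the crash metric to hypoxic records
#'
#' The crash indicator distinguishes hypoxic measurements made before versus
#' after the animal first reaches its critical oxygen concentration: 1 for
#' records strictly preceding the first record at or below `ccrit`, 0 from
#' that record onward. Records are assumed ordered by time.
#'
#' @param records Data frame of hypoxic records with `mean_o2_conc`.
#' @param ccrit Critical oxygen concentration, mg l-1.
#' @return Integer vector of 0/1 crash values.
#' @export
assign_crash <- function(records, ccrit) {
  o2 <- records$mean_o2_conc
  n <- length(o2)
  if (n == 0L) return(integer())
  reached <- which(o2 <= ccrit)
  if (length(reached) == 0L) return(rep(1L, n))
  ifelse(seq_len(n) < reached[1], 1L, 0L)
}

#' Join MO2 records with per-period activity and animal metadata
#'
#' One row per QC-passing MO2 record, keyed on `period_index`. Activity
#' fields are `NA` for periods without acceleration coverage. The crash
#' metric is filled for hypoxic records from the critical oxygen result
#' (and is `NA` for normoxic records).
#'
#' @param mo2_records Output of [fit_mo2_records()] (background-corrected).
#' @param period_activity Output of [activity_by_period()] /
#'   [aggregate_by_period()], or NULL.
#' @param crit A `crit_oxygen` object or NULL.
#' @param animal_id Animal identifier.
#' @param temperature Treatment temperature, degrees C.
#' @param total_length Total length, cm.
#' @return Data frame of aligned records.
#' @export
align_records <- function(mo2_records, period_activity = NULL, crit = NULL,
                          animal_id = "A1", temperature = NA_real_,
                          total_length = NA_real_) {
  if (anyDuplicated(mo2_records$period_index))
    stop("duplicate period indices in MO2 records")
  if (!is.null(period_activity) &&
      anyDuplicated(period_activity$period_index))
    stop("duplicate period indices in activity records")
  rec <- mo2_records[mo2_records$qc_pass, , drop = FALSE]
  out <- data.frame(
    animal_id = animal_id, temperature = temperature,
    period_index = rec$period_index, mo2 = rec$mo2,
    mean_o2_conc = rec$mean_o2_conc, mean_o2_sat = rec$mean_o2_sat,
    tbf = NA_real_, tbaa = NA_real_, odba = NA_real_,
    total_length = total_length,
    hours_since_chase = rec$mid_time / 3600,
    phase = rec$phase, crash = NA_integer_
  )
  if (!is.null(period_activity) && nrow(period_activity) > 0) {
    m <- match(out$period_index, period_activity$period_index)
    out$tbf <- period_activity$mean_tbf[m]
    out$tbaa <- period_activity$mean_tbaa[m]
    out$odba <- period_activity$mean_odba[m]
  }
  hyp <- out$phase == "hypoxic"
  if (any(hyp) && !is.null(crit) && isTRUE(crit$found)) {
    out$crash[hyp] <- assign_crash(out[hyp, , drop = FALSE], crit$ccrit)
  }
  out
}

build_formula <- function(response, covariates, interactions = NULL) {
  terms <- c(covariates, interactions)
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit an activity-metabolism mixed model
#'
#' Linear model of metabolic rate on the chosen covariates with animal-level
#' random intercepts, optional first-order autoregressive serial correlation
#' within animal (over period order) and optional per-temperature residual
#' variances, fitted by maximum likelihood (nlme) so BIC is comparable
#' across candidate fixed-effect structures on identical data. Degenerate
#' zero-residual data fall back to ordinary least squares.
#'
#' @param data Aligned records (see [align_records()]); must contain
#'   `animal_id`, `period_index` and the model variables.
#' @param covariates Character vector of fixed-effect terms.
#' @param interactions Optional character vector like `"tbf:temperature"`.
#' @param response Response column. Default `"mo2"`.
#' @param ar1 Model within-animal AR(1) serial correlation? Default TRUE.
#' @param var_by_temperature Separate residual variance per temperature?
#'   Default FALSE.
#' @return List of class `fit_result`: `coefficients` (estimate, std.error),
#'   `bic`, `n_obs`, `n_params`, `converged`, `spec`, `model`.
#' @export
fit_model <- function(data, covariates, interactions = NULL,
                      response = "mo2", ar1 = TRUE,
                      var_by_temperature = FALSE) {
  if (length(unique(data$animal_id)) < 2L)
    stop("need at least 2 animals to separate animal and residual variation")
  if (nrow(data) < 10L) stop("need at least 10 rows")
  form <- build_formula(response, covariates, interactions)
  spec <- list(response = response, covariates = covariates,
               interactions = interactions, ar1 = ar1,
               var_by_temperature = var_by_temperature)
  data <- data[stats::complete.cases(
    data[, unique(c(response, covariates,
                    unlist(strsplit(interactions %||% character(), ":")),
                    "animal_id", "period_index")), drop = FALSE]), ,
    drop = FALSE]
  # an (essentially) exact linear fit defeats mixed-model variance
  # estimation; OLS then recovers the generating coefficients directly
  ols <- stats::lm(form, data = data)
  y <- data[[response]]
  if (stats::sigma(ols) <= 1e-7 * max(1, mean(abs(y)))) {
    ct <- suppressWarnings(summary(ols))$coefficients
    return(structure(list(
      coefficients = data.frame(term = rownames(ct), estimate = ct[, 1],
                                std.error = ct[, 2]),
      bic = stats::BIC(ols), n_obs = nrow(data),
      n_params = length(stats::coef(ols)) + 1L,
      converged = TRUE, spec = spec, model = ols,
      note = "ols_degenerate_exact_fit"), class = "fit_result"))
  }
  args <- list(
    fixed = form, random = ~ 1 | animal_id, data = data, method = "ML",
    control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                               returnObject = TRUE))
  if (ar1)
    args$correlation <- nlme::corAR1(form = ~ period_index | animal_id)
  if (var_by_temperature)
    args$weights <- nlme::varIdent(form = ~ 1 | temperature)
  # zero within-animal residual variance makes the mixed likelihood
  # unbounded and the optimiser unreliable; the (balanced) OLS solution is
  # the correct degenerate limit
  r <- stats::resid(ols)
  within_sd <- stats::sd(r - stats::ave(r, data$animal_id))
  if (is.na(within_sd) || within_sd <= 1e-7 * max(1, mean(abs(y)))) {
    ct <- suppressWarnings(summary(ols))$coefficients
    return(structure(list(
      coefficients = data.frame(term = rownames(ct), estimate = ct[, 1],
                                std.error = ct[, 2]),
      bic = stats::BIC(ols), n_obs = nrow(data),
      n_params = length(stats::coef(ols)) + 1L,
      converged = TRUE, spec = spec, model = ols,
      note = "ols_degenerate_within_animal"), class = "fit_result"))
  }
  # the mixed model nests OLS (zero random variance, no correlation), so a
  # maximum-likelihood fit whose logLik falls below the OLS boundary value
  # has not converged, whatever the optimiser reports
  ll_floor <- as.numeric(stats::logLik(ols)) - 1e-6
  fit <- tryCatch(suppressWarnings(do.call(nlme::lme, args)),
                  error = function(e) e)
  if (inherits(fit, "error") ||
      as.numeric(stats::logLik(fit)) < ll_floor) {
    # retry with the slower, more forgiving optimiser before giving up
    args$control <- nlme::lmeControl(opt = "optim", maxIter = 200,
                                     msMaxIter = 200, returnObject = TRUE)
    fit <- tryCatch(suppressWarnings(do.call(nlme::lme, args)),
                    error = function(e) e)
  }
  if (!inherits(fit, "error") &&
      as.numeric(stats::logLik(fit)) < ll_floor) {
    ct <- suppressWarnings(summary(ols))$coefficients
    return(structure(list(
      coefficients = data.frame(term = rownames(ct), estimate = ct[, 1],
                                std.error = ct[, 2]),
      bic = stats::BIC(ols), n_obs = nrow(data),
      n_params = length(stats::coef(ols)) + 1L,
      converged = TRUE, spec = spec, model = ols,
      note = "ols_fallback_nonconvergence"), class = "fit_result"))
  }
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, bic = Inf, n_obs = nrow(data),
                          n_params = NA_integer_, converged = FALSE,
                          spec = spec, model = NULL,
                          note = conditionMessage(fit)),
                     class = "fit_result"))
  }
  ct <- summary(fit)$tTable
  structure(list(
    coefficients = data.frame(term = rownames(ct), estimate = ct[, "Value"],
                              std.error = ct[, "Std.Error"]),
    bic = stats::BIC(fit), n_obs = nrow(data),
    n_params = attr(stats::logLik(fit), "df"),
    converged = TRUE, spec = spec, model = fit), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("mixed model fit: %s | BIC %.1f | n = %d | converged: %s\n",
              deparse(build_formula(x$spec$response, x$spec$covariates,
                                    x$spec$interactions)),
              x$bic, x$n_obs, x$converged))
  if (!is.null(x$coefficients)) print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Rank candidate models by BIC
#'
#' Fits every candidate covariate set on the same rows and ranks by BIC;
#' candidates within 2 BIC units of each other are resolved toward fewer
#' parameters (then input order).
#'
#' @param data Aligned records.
#' @param candidates List of candidate specs, each a list with `covariates`
#'   and optionally `interactions`.
#' @param ... Passed to [fit_model()] (e.g. `ar1`, `var_by_temperature`).
#' @return List with `table` (data frame: candidate, covariates, bic,
#'   n_params, converged, rank), `chosen` (index into `candidates`) and
#'   `fits`.
#' @export
select_by_bic <- function(data, candidates, ...) {
  if (length(candidates) < 2L) stop("need at least 2 candidate models")
  fits <- lapply(candidates, function(cand) {
    fit_model(data, covariates = cand$covariates,
              interactions = cand$interactions, ...)
  })
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  npar <- vapply(fits, function(f) as.numeric(f$n_params %||% NA), numeric(1))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("no candidate model converged")
  ord <- order(bic, npar, seq_along(fits))
  # within 2 BIC units of the best, prefer the most parsimonious
  best_bic <- min(bic[conv])
  tied <- which(conv & bic <= best_bic + 2)
  chosen <- tied[order(npar[tied], tied)][1]
  tab <- data.frame(
    candidate = seq_along(fits),
    covariates = vapply(candidates, function(cand)
      paste(c(cand$covariates, cand$interactions), collapse = "+"),
      character(1)),
    bic = bic, n_params = npar, converged = conv)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  list(table = tab, chosen = chosen, fits = fits)
}

#' Cluster-bootstrap prediction intervals
#'
#' Resamples animals with replacement (keeping each animal's rows together),
#' refits the model and predicts the population-level response on a
#' covariate grid; percentile 95% intervals across bootstrap replicates.
#'
#' @param data Aligned records.
#' @param covariates,interactions,response,ar1,var_by_temperature As
#'   [fit_model()].
#' @param grid Data frame of covariate values to predict at; defaults to a
#'   single row at the observed covariate means.
#' @param n_boot Bootstrap replicates. Default 1000 (warning below 100).
#' @param seed RNG seed.
#' @return List with `grid` (predictions: fit, lwr, upr), `n_boot`, and the
#'   matrix of bootstrap predictions.
#' @export
bootstrap_predictions <- function(data, covariates, interactions = NULL,
                                  response = "mo2", ar1 = TRUE,
                                  var_by_temperature = FALSE, grid = NULL,
                                  n_boot = 1000, seed = 1L) {
  if (n_boot < 100) warning("n_boot below 100; intervals will be unstable")
  set.seed(seed)
  vars <- unique(c(covariates,
                   unlist(strsplit(interactions %||% character(), ":"))))
  if (is.null(grid)) {
    grid <- as.data.frame(lapply(data[, vars, drop = FALSE],
                                 function(v) mean(v, na.rm = TRUE)))
  }
  base_fit <- fit_model(data, covariates, interactions, response, ar1,
                        var_by_temperature)
  animals <- unique(data$animal_id)
  rows_of <- split(seq_len(nrow(data)), data$animal_id)
  preds <- matrix(NA_real_, nrow = n_boot, ncol = nrow(grid))
  for (b in seq_len(n_boot)) {
    take <- sample(animals, length(animals), replace = TRUE)
    idx <- rows_of[take]
    boot <- data[unlist(idx), , drop = FALSE]
    boot$animal_id <- rep(paste0("boot", seq_along(take)), lengths(idx))
    fit <- tryCatch(
      fit_model(boot, covariates, interactions, response, ar1,
                var_by_temperature),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) next
    preds[b, ] <- predict_population(fit, grid)
  }
  ok <- stats::complete.cases(preds)
  # percentile interval endpoints as the (B+1)*alpha order statistics
  # (quantile type 6), the standard bootstrap convention; the default
  # type-7 quantiles are biased inward in the tails at moderate B
  qs <- apply(preds[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), type = 6)
  grid$fit <- predict_population(base_fit, grid)
  grid$lwr <- qs[1, ]
  grid$upr <- qs[2, ]
  list(grid = grid, n_boot = n_boot, n_used = sum(ok), predictions = preds)
}

predict_population <- function(fit, grid) {
  if (inherits(fit$model, "lm")) return(unname(stats::predict(fit$model, grid)))
  unname(stats::predict(fit$model, grid, level = 0))
}

#' Paired temperature contrasts of metabolic metrics
#'
#' For each metric and each pair of treatment temperatures, the estimated
#' difference (second minus first), its 95% interval and p-value from a
#' mixed model with a random animal intercept (estimated marginal means).
#'
#' @param summaries Data frame with one row per animal x temperature:
#'   `animal_id`, `temperature`, and metric columns.
#' @param metrics Metric columns to contrast. Default
#'   `c("mmr", "mrmr", "aerobic_scope", "pcrit")`.
#' @return Data frame: `metric`, `pair`, `estimate`, `lower`, `upper`,
#'   `p_value`.
#' @export
temperature_contrasts <- function(summaries,
                                  metrics = c("mmr", "mrmr",
                                              "aerobic_scope", "pcrit")) {
  stopifnot(all(c("animal_id", "temperature") %in% names(summaries)))
  temps <- sort(unique(summaries$temperature))
  if (length(temps) < 2L) stop("need at least 2 temperatures")
  per_animal <- table(summaries$animal_id)
  if (sum(per_animal >= 2) < 2L)
    stop("need at least 2 animals measured at 2 or more temperatures")
  out <- list()
  for (m in metrics) {
    d <- summaries[!is.na(summaries[[m]]), , drop = FALSE]
    d$temp_f <- factor(d$temperature)
    d$y <- d[[m]]
    fit <- tryCatch(
      nlme::lme(y ~ temp_f, random = ~ 1 | animal_id, data = d,
                method = "REML",
                control = nlme::lmeControl(opt = "optim",
                                           returnObject = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("contrast model for %s failed to fit; skipped", m))
      next
    }
    emm <- emmeans::emmeans(fit, "temp_f")
    ctr <- emmeans::contrast(emm, method = "revpairwise", adjust = "none")
    cs <- as.data.frame(stats::confint(ctr))
    ps <- as.data.frame(ctr)
    out[[length(out) + 1L]] <- data.frame(
      metric = m,
      pair = gsub("temp_f| ", "", cs$contrast),
      estimate = cs$estimate, lower = cs$lower.CL, upper = cs$upper.CL,
      p_value = ps$p.value
    )
  }
  do.call(rbind, out)
}
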