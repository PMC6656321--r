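#' Maximum metabolic rate from the normoxic record set
#'
#' Mean of the 10% highest metabolic-rate measurements over the normoxia
#' period (`k = max(1, round-half-up(quantile x n))` records), a deliberately
#' outlier-resistant alternative to taking the single highest record.
#'
#' @param records Data frame of QC-passing normoxic MO2 records (or a
#'   numeric vector of rates).
#' @param quantile Fraction of records entering the mean. Default 0.10.
#' @return List with `mmr`, `k` and `indices` (rows used).
#' @examples
#' compute_mmr(1:40)$mmr  # mean of 37:40 = 38.5
#' @export
compute_mmr <- function(records, quantile = 0.10) {
  mo2 <- if (is.data.frame(records)) records$mo2 else as.numeric(records)
  n <- length(mo2)
  if (n == 0L) stop("no records supplied")
  k <- quantile_k(n, quantile)
  idx <- order(mo2, decreasing = TRUE)[seq_len(k)]
  list(mmr = mean(mo2[idx]), k = k, indices = idx)
}

#' Minimum routine metabolic rate from the normoxic record set
#'
#' Mean of the 10% lowest normoxic measurements; the routine-rate floor that
#' stands in for standard metabolic rate in fishes that must swim
#' continuously to ventilate.
#'
#' @inheritParams compute_mmr
#' @return List with `mrmr`, `k` and `indices`.
#' @examples
#' compute_mrmr(1:40)$mrmr  # mean of 1:4 = 2.5
#' @export
compute_mrmr <- function(records, quantile = 0.10) {
  mo2 <- if (is.data.frame(records)) records$mo2 else as.numeric(records)
  n <- length(mo2)
  if (n == 0L) stop("no records supplied")
  k <- quantile_k(n, quantile)
  idx <- order(mo2)[seq_len(k)]
  list(mrmr = mean(mo2[idx]), k = k, indices = idx)
}

#' Metabolic summary: MMR, mRMR and aerobic scope
#'
#' @param records QC-passing normoxic MO2 records.
#' @param quantile Fraction for the top/bottom means. Default 0.10.
#' @return One-row data frame: `mmr`, `mrmr`, `aerobic_scope`,
#'   `n_records_used`, `k_top`, `k_bottom`.
#' @export
metabolic_summary <- function(records, quantile = 0.10) {
  hi <- compute_mmr(records, quantile)
  lo <- compute_mrmr(records, quantile)
  data.frame(
    mmr = hi$mmr, mrmr = lo$mrmr, aerobic_scope = hi$mmr - lo$mrmr,
    n_records_used = if (is.data.frame(records)) nrow(records)
                     else length(records),
    k_top = hi$k, k_bottom = lo$k
  )
}

#' Critical oxygen level by regression against the routine-rate floor
#'
#' Implements the suffix rule: find the first hypoxic record whose metabolic
#' rate drops below `mrmr` with all later records also below it, regress
#' those rates on their oxygen concentrations, and define C_crit as the
#' oxygen concentration where the regression line meets `mrmr`. S_crit and
#' P_crit follow through the solubility and partial-pressure conversions.
#'
#' @param records Hypoxic MO2 records ordered by time, carrying
#'   `mean_o2_conc`.
#' @param mrmr Reference minimum routine metabolic rate (mg O2 kg-1 h-1).
#' @param conditions A [gas_conditions()] for the S_crit/P_crit conversions.
#' @param method `"suffix"` (default, the rule above) or `"two_segment"`, an
#'   optional two-segment least-squares breakpoint variant.
#' @return An object of class `crit_oxygen`: list with `found`, `ccrit`,
#'   `scrit` (fraction), `pcrit` (mmHg), `regression_slope`,
#'   `regression_intercept`, `n_points`, `mrmr_ref`, `indices`, and `reason`
#'   when not found.
#' @examples
#' rec <- data.frame(mo2 = c(160, 155, 140, 120, 100),
#'                   mean_o2_conc = c(5, 4, 3, 2.5, 2))
#' detect_crit(rec, mrmr = 150, gas_conditions(28))$ccrit  # 3.25
#' @export
detect_crit <- function(records, mrmr, conditions,
                        method = c("suffix", "two_segment")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records), mrmr > 0,
            inherits(conditions, "gas_conditions"))
  if (method == "two_segment") return(detect_crit_two_segment(records, mrmr, conditions))
  n <- nrow(records)
  below <- records$mo2 < mrmr
  if (n == 0L || !below[n] || !any(below))
    return(crit_not_found(mrmr, "no terminal run of records below mrmr"))
  start <- if (all(below)) 1L else max(which(!below)) + 1L
  idx <- start:n
  if (length(idx) < 2L)
    return(crit_not_found(mrmr, "fewer than 2 records below mrmr"))
  fit <- ols_fit(records$mean_o2_conc[idx], records$mo2[idx])
  if (fit$slope <= 0)
    return(crit_not_found(
      mrmr, "non-positive conformity slope; intersection behind the data"))
  ccrit <- (mrmr - fit$intercept) / fit$slope
  crit_oxygen(ccrit, conditions, fit$slope, fit$intercept,
              n_points = length(idx), mrmr_ref = mrmr, indices = idx)
}

crit_oxygen <- function(ccrit, conditions, slope, intercept, n_points,
                        mrmr_ref, indices) {
  scrit <- ccrit / o2_saturation_concentration(conditions)
  structure(
    list(found = TRUE, ccrit = ccrit, scrit = scrit,
         pcrit = scrit * ambient_po2(conditions),
         regression_slope = slope, regression_intercept = intercept,
         n_points = n_points, mrmr_ref = mrmr_ref, indices = indices,
         conditions = conditions),
    class = "crit_oxygen"
  )
}

crit_not_found <- function(mrmr, reason) {
  structure(
    list(found = FALSE, ccrit = NA_real_, scrit = NA_real_,
         pcrit = NA_real_, regression_slope = NA_real_,
         regression_intercept = NA_real_, n_points = 0L,
         mrmr_ref = mrmr, indices = integer(), reason = reason),
    class = "crit_oxygen"
  )
}

# optional variant: free two-segment least squares over candidate splits,
# breakpoint at the intersection of the two fitted lines
detect_crit_two_segment <- function(records, mrmr, conditions) {
  n <- nrow(records)
  if (n < 4L) return(crit_not_found(mrmr, "too few records for two segments"))
  o2 <- records$mean_o2_conc; mo2 <- records$mo2
  ord <- order(o2, decreasing = TRUE)
  o2 <- o2[ord]; mo2 <- mo2[ord]
  best <- NULL; best_sse <- Inf
  for (split in 2:(n - 2L)) {
    hi <- seq_len(split); lo <- (split + 1L):n
    f1 <- ols_fit(o2[hi], mo2[hi]); f2 <- ols_fit(o2[lo], mo2[lo])
    sse <- sum((mo2[hi] - f1$intercept - f1$slope * o2[hi])^2) +
      sum((mo2[lo] - f2$intercept - f2$slope * o2[lo])^2)
    if (sse < best_sse) { best_sse <- sse; best <- list(f1 = f1, f2 = f2, lo = lo) }
  }
  f2 <- best$f2
  if (f2$slope <= 0)
    return(crit_not_found(mrmr, "non-positive conformity slope"))
  ccrit <- (mrmr - f2$intercept) / f2$slope
  crit_oxygen(ccrit, conditions, f2$slope, f2$intercept,
              n_points = length(best$lo), mrmr_ref = mrmr,
              indices = ord[best$lo])
}

#' @export
print.crit_oxygen <- function(x, ...) {
  if (!x$found) {
    cat("critical oxygen level: not found (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "critical oxygen level: C_crit %.2f mg/l | S_crit %.1f%% | P_crit %.1f mmHg (n = %d)\n",
      x$ccrit, 100 * x$scrit, x$pcrit, x$n_points))
  }
  invisible(x)
}
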