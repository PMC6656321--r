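#' @keywords internal
"_PACKAGE"

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# number of records entering the top/bottom 10% mean: floor of 1
quantile_k <- function(n, quantile = 0.10) {
  stopifnot(n >= 1, quantile > 0, quantile < 1)
  max(1L, as.integer(round_half_up(quantile * n)))
}

# simple OLS of y on x returning slope, intercept, r2; r2 of a
# zero-variance response is defined as 0 (degenerate fit, never "perfect")
ols_fit <- function(x, y) {
  if (length(x) < 2L) stop("need at least 2 points for a regression")
  if (stats::var(x) == 0) stop("predictor is constant; slope undefined")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  syy <- sum((y - my)^2)
  r2 <- if (syy == 0) 0 else (sxy^2 / (sxx * syy))
  list(slope = slope, intercept = intercept, r_squared = r2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# centred moving average with truncated windows at the edges;
# exact pass-through for constant and (interior) linear inputs
moving_average <- function(x, width) {
  n <- length(x)
  width <- as.integer(width)
  stopifnot(width >= 1L, n >= 1L)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
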