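#' Hjorth parameters
#'
#' Activity is the signal variance; mobility is the standard-deviation ratio
#' of the first difference to the signal; complexity is the mobility of the
#' first difference divided by the mobility of the signal. Derivatives are
#' taken as plain first differences: mobility and complexity are ratios, so
#' the sampling-interval factor cancels.
#'
#' @param x numeric vector, length >= 3, finite.
#' @return named numeric vector `c(activity, mobility, complexity)`. For a
#'   zero-variance signal, mobility and complexity are 0 by convention.
#' @export
hjorth <- function(x) {
  n <- length(x)
  if (n < 3L) stop("hjorth needs at least 3 samples")
  v0 <- stats::var(x)
  if (v0 == 0) return(c(activity = 0, mobility = 0, complexity = 0))
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 == 0) return(c(activity = v0, mobility = 0, complexity = 0))
  v2 <- stats::var(d2)
  cplx <- sqrt(v2 / v1) / mob
  c(activity = v0, mobility = mob, complexity = cplx)
}

#' The 24 time-domain features of one channel
#'
#' Amplitude and shape descriptors of a single-channel EEG segment: extrema,
#' moments, integrated amplitude measures, waveform-length measures, the
#' Hjorth parameters, quartiles, and threshold-free zero-crossing and
#' slope-sign-change counts.
#'
#' Conventions: standard deviation and variance use the sample (N-1)
#' denominator; kurtosis is the non-excess biased estimator (a normal signal
#' gives ~3) and skewness the biased estimator; `ieeg = sum(|x|)`,
#' `mav = ieeg/N`, `ssi = sum(x^2)`, `rms = sqrt(ssi/N)`,
#' `wl = sum(|diff(x)|)`, `aac = wl/(N-1)`, `dasdv = sqrt(sum(diff(x)^2)/(N-1))`;
#' the mode is the most frequent value after rounding to `mode_digits`
#' decimals (ties broken toward the smallest value); quartiles interpolate
#' linearly between order statistics; zero crossings count strict sign
#' products `x[i]*x[i+1] < 0` and slope-sign changes count strict products of
#' consecutive differences.
#'
#' @param x numeric vector, length >= 3, all finite.
#' @param mode_digits decimal places used to discretize the signal before
#'   taking the mode (default 2).
#' @return named numeric vector of length 24 in the order of
#'   [temporal_feature_names()].
#' @export
#' @examples
#' temporal_features(c(1, 2, 3))[c("mean", "sd", "wl", "range")]
temporal_features <- function(x, mode_digits = 2L) {
  n <- length(x)
  if (n < 3L) stop("temporal features need at least 3 samples")
  if (!all(is.finite(x))) stop("non-finite values in signal")
  d <- diff(x)
  mn <- min(x); mx <- max(x); mu <- mean(x)
  v <- stats::var(x); s <- sqrt(v)
  ieeg <- sum(abs(x))
  ssi <- sum(x^2)
  wl <- sum(abs(d))
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    kur <- mean((x - mu)^4) / m2^2
    ske <- mean((x - mu)^3) / m2^1.5
  } else {
    kur <- 0; ske <- 0
  }
  hj <- hjorth(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  r <- round(x, mode_digits)
  tab <- table(r)
  mode_val <- min(as.numeric(names(tab)[tab == max(tab)]))
  zc <- sum(x[-n] * x[-1L] < 0)
  ssc <- if (n >= 3L) sum(d[-(n - 1L)] * d[-1L] < 0) else 0L
  out <- c(mn, mx, mu, s, ieeg, ieeg / n, ssi, v, sqrt(ssi / n),
           wl, wl / (n - 1), sqrt(sum(d^2) / (n - 1)),
           mode_val, kur, ske,
           hj[["activity"]], hj[["mobility"]], hj[["complexity"]],
           q[1L], q[2L], q[3L], zc, ssc, mx - mn)
  names(out) <- temporal_feature_names()
  out
}
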