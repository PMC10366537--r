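#' Lagged Poincare plot dispersions SD1 and SD2
#'
#' The m-lagged Poincare plot scatters each sample `x[i]` against
#' `x[i + m]`. Rotating the cloud by 45 degrees gives
#' `xa = (x[i+m] - x[i])/sqrt(2)` and `xb = (x[i+m] + x[i])/sqrt(2)`;
#' SD1 and SD2 are the sample standard deviations of `xa` and `xb`: the
#' minor-axis (short-term) and major-axis (long-term) dispersions of the
#' fitted ellipse.
#'
#' @param x numeric vector with `length(x) >= lag + 3` (at least three plot
#'   points).
#' @param lag positive integer lag m.
#' @return named numeric vector `c(SD1, SD2)`.
#' @export
#' @examples
#' poincare_sd(c(1, 2, 3, 4, 5), lag = 1)  # SD1 = 0 on an arithmetic ramp
poincare_sd <- function(x, lag) {
  lag <- as.integer(lag)
  stopifnot(lag >= 1L)
  n <- length(x)
  if (n < lag + 3L) {
    stop(sprintf("signal length %d too short for lag %d (need >= %d)",
                 n, lag, lag + 3L))
  }
  xi <- x[1:(n - lag)]
  xl <- x[(1 + lag):n]
  xa <- (xl - xi) / sqrt(2)
  xb <- (xl + xi) / sqrt(2)
  c(SD1 = stats::sd(xa), SD2 = stats::sd(xb))
}

#' Poincare descriptors over a set of lags
#'
#' For each lag m: SD1, SD2, their product SD1*SD2 (proportional to the
#' ellipse area) and their ratio SD1/SD2 (cloud shape; near 1 for an
#' uncorrelated series). A degenerate cloud with SD2 = 0 reports the ratio
#' as 0 rather than NaN so feature matrices stay finite.
#'
#' @param x numeric vector.
#' @param lags integer vector of lags (default `c(1, 9)`).
#' @return named numeric vector of `4 * length(lags)` values named
#'   `lag<m>_SD1`, `lag<m>_SD2`, `lag<m>_SD1xSD2`, `lag<m>_SD1dSD2`.
#' @export
poincare_features <- function(x, lags = c(1L, 9L)) {
  out <- numeric(0)
  for (m in lags) {
    sds <- poincare_sd(x, m)
    sd1 <- sds[["SD1"]]; sd2 <- sds[["SD2"]]
    ratio <- if (sd2 > 0) sd1 / sd2 else 0
    v <- c(sd1, sd2, sd1 * sd2, ratio)
    names(v) <- paste0(sprintf("lag%d_", m),
                       c("SD1", "SD2", "SD1xSD2", "SD1dSD2"))
    out <- c(out, v)
  }
  out
}
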