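#' DFT bin indices of a frequency band
#'
#' Returns the 0-based one-sided DFT bin indices `k` whose frequencies
#' `k*fs/N` fall in the half-open interval `[low_hz, high_hz)`. The half-open
#' convention guarantees adjacent bands never share a bin.
#'
#' @param fs sampling rate in Hz.
#' @param n signal length in samples.
#' @param band one-row band definition (list or data.frame row with `name`,
#'   `low_hz`, `high_hz`).
#' @return integer vector of 0-based bin indices.
#' @export
#' @examples
#' band_bins(250, 750, list(name = "alpha", low_hz = 8, high_hz = 13)) # 24:38
band_bins <- function(fs, n, band) {
  stopifnot(fs > 0, n >= 2)
  if (band$high_hz > fs / 2 + 1e-12) {
    stop(sprintf("band %s: high edge %g Hz exceeds the Nyquist frequency %g Hz",
                 band$name, band$high_hz, fs / 2))
  }
  k <- 0:(floor(n / 2))
  freq <- k * fs / n
  idx <- k[freq >= band$low_hz & freq < band$high_hz]
  if (length(idx) == 0L) {
    stop(sprintf("band %s captures no DFT bins at fs=%g, n=%d",
                 band$name, fs, n))
  }
  as.integer(idx)
}

#' FFT subband energy, variance and entropy
#'
#' For each band, with `Y_k` the one-sided DFT coefficients of the channel
#' restricted to the band's bins: energy is `sum(|Y_k|^2)`; variance is the
#' sample variance of the magnitudes `|Y_k|`; entropy is the normalized
#' Shannon entropy `-(1/log M) * sum(p_k log p_k)` of the in-band power
#' weights `p_k = |Y_k|^2 / energy`, so it lies in \[0, 1\] (1 for a flat
#' in-band spectrum, near 0 for a single line). A band with zero energy has
#' entropy 0 by convention; a single-bin band has variance 0 with a warning.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param bands band table as from [default_bands()].
#' @param window `"none"` (default) or `"hann"` taper before the FFT.
#' @return named numeric vector with entries `<band>_energy`,
#'   `<band>_variance`, `<band>_entropy` per band.
#' @export
fft_band_features <- function(x, fs, bands = default_bands(),
                              window = c("none", "hann")) {
  window <- match.arg(window)
  validate_bands(bands)
  n <- length(x)
  if (window == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
  }
  Y <- stats::fft(x)
  total_power <- sum(Mod(Y)^2)
  out <- numeric(0)
  for (b in seq_len(nrow(bands))) {
    band <- bands[b, ]
    idx <- band_bins(fs, n, band)
    mag <- Mod(Y[idx + 1L])           # 0-based bin -> 1-based R index
    pw <- mag^2
    energy <- sum(pw)
    # numerical noise floor: a band whose share of the total power is at
    # round-off level (e.g. the FFT of a constant) counts as empty
    if (energy <= 1e-20 * total_power) energy <- 0
    if (length(mag) > 1L) {
      variance <- stats::var(mag)
    } else {
      warning(sprintf("band %s has a single DFT bin; variance set to 0",
                      band$name))
      variance <- 0
    }
    if (energy > 0) {
      p <- pw / energy
      p <- p[p > 0]
      entropy <- -sum(p * log(p)) / log(length(mag))
    } else {
      entropy <- 0
    }
    v <- c(energy, variance, entropy)
    names(v) <- paste0(band$name, c("_energy", "_variance", "_entropy"))
    out <- c(out, v)
  }
  out
}
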