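# Haar wavelet-packet decomposition. The orthonormal Haar analysis step maps
# a pair (x1, x2) to the approximation (x1+x2)/sqrt(2) and the detail
# (x2-x1)/sqrt(2); applied recursively to every node it yields the full
# packet tree, whose terminal nodes tile [0, fs/2) in uniform subbands once
# the natural (Paley) node order is remapped to frequency order.

# internal: natural-order -> frequency-order permutation at a given level.
# Node paths are bit strings a_1..a_L (0 = lowpass); the frequency index has
# bits b_i = xor(a_i, b_{i-1}) (binary-reflected Gray decoding), because each
# highpass branch mirrors the frequency axis of its subtree.
.wpd_order_cache <- new.env(parent = emptyenv())

wpd_freq_order <- function(level) {
  key <- as.character(level)
  cached <- .wpd_order_cache[[key]]
  if (!is.null(cached)) return(cached)
  n_nodes <- 2L^level
  natural <- 0:(n_nodes - 1L)
  freq <- integer(n_nodes)
  for (n in natural) {
    b_prev <- 0L
    f <- 0L
    for (i in seq_len(level)) {
      a <- bitwAnd(bitwShiftR(n, level - i), 1L)
      b <- bitwXor(a, b_prev)
      f <- bitwOr(bitwShiftL(f, 1L), b)
      b_prev <- b
    }
    freq[n + 1L] <- f
  }
  .wpd_order_cache[[key]] <- freq
  freq
}

#' Haar wavelet (packet) decomposition
#'
#' Decomposes a signal with orthonormal Haar filters. In `"wpd"` mode
#' (default) the full packet tree is built to the requested level and the
#' `2^level` terminal nodes are returned in frequency order, node `n`
#' (0-based) spanning `[n, n+1) * fs / 2^(level+1)` Hz. In `"dwt"` mode only
#' the approximation chain is split, giving `level + 1` dyadic subbands.
#' Signals whose length is not a multiple of `2^level` are zero-padded up to
#' the next multiple; the padding only adds (near-)zero coefficients.
#'
#' @param x numeric vector with `length(x) >= 2^level`.
#' @param level decomposition depth (>= 1).
#' @param wavelet mother wavelet; only `"haar"`.
#' @param fs sampling rate in Hz, used to annotate node frequency spans.
#' @param mode `"wpd"` or `"dwt"`.
#' @return An object of class `wpd_decomposition`: list with `nodes` (list of
#'   coefficient vectors in increasing-frequency order), `node_freqs`
#'   (data.frame `low_hz`, `high_hz`, `center_hz` per node), `level`, `mode`,
#'   `n` (original length), `n_padded`.
#' @export
#' @examples
#' w <- wpd(c(1, 3), level = 1, fs = 2)
#' w$nodes  # approximation 2*sqrt(2), detail sqrt(2)
wpd <- function(x, level, wavelet = "haar", fs = 2, mode = c("wpd", "dwt")) {
  mode <- match.arg(mode)
  wavelet <- match.arg(wavelet, "haar")
  level <- as.integer(level)
  stopifnot(level >= 1L)
  n <- length(x)
  block <- 2L^level
  if (n < block) {
    stop(sprintf("signal length %d is shorter than 2^level = %d", n, block))
  }
  n_pad <- as.integer(ceiling(n / block) * block)
  if (n_pad > n) x <- c(x, numeric(n_pad - n))

  haar_step <- function(v) {
    odd <- v[seq(1L, length(v), by = 2L)]
    even <- v[seq(2L, length(v), by = 2L)]
    list(a = (odd + even) / sqrt(2), d = (even - odd) / sqrt(2))
  }

  if (mode == "wpd") {
    # vectorized packet tree: columns are nodes in natural (Paley) order
    m <- matrix(x, ncol = 1L)
    for (l in seq_len(level)) {
      half <- nrow(m) / 2L
      nb <- ncol(m)
      odd <- m[seq(1L, nrow(m), by = 2L), , drop = FALSE]
      even <- m[seq(2L, nrow(m), by = 2L), , drop = FALSE]
      out <- matrix(0, half, 2L * nb)
      out[, seq(1L, 2L * nb, by = 2L)] <- (odd + even) / sqrt(2)
      out[, seq(2L, 2L * nb, by = 2L)] <- (even - odd) / sqrt(2)
      m <- out
    }
    nodes <- lapply(seq_len(ncol(m)), function(j) m[, j])
    # natural order -> frequency order
    perm <- wpd_freq_order(level)
    ordered <- vector("list", length(nodes))
    for (i in seq_along(nodes)) ordered[[perm[i] + 1L]] <- nodes[[i]]
    width <- fs / 2^(level + 1L)
    nf <- data.frame(low_hz = (seq_along(ordered) - 1L) * width,
                     high_hz = seq_along(ordered) * width)
  } else {
    a <- x
    details <- vector("list", level)
    for (l in seq_len(level)) {
      s <- haar_step(a)
      a <- s$a
      details[[l]] <- s$d
    }
    # increasing frequency: a_L, d_L, d_{L-1}, ..., d_1
    ordered <- c(list(a), rev(details))
    lows <- c(0, fs / 2^((level:1) + 1L))
    highs <- c(fs / 2^((level + 1L):1))
    nf <- data.frame(low_hz = lows, high_hz = highs)
  }
  nf$center_hz <- (nf$low_hz + nf$high_hz) / 2
  structure(list(nodes = ordered, node_freqs = nf, level = level,
                 mode = mode, n = n, n_padded = n_pad),
            class = "wpd_decomposition")
}

#' @export
print.wpd_decomposition <- function(x, ...) {
  cat(sprintf("<wpd_decomposition> %s level %d: %d nodes, %d samples (%d padded)\n",
              x$mode, x$level, length(x$nodes), x$n, x$n_padded))
  invisible(x)
}

# internal: assign node center frequencies to bands. A node whose center
# falls below the lowest band edge is folded into the lowest band (so DC and
# slow drift land in delta rather than nowhere); centers above the highest
# band edge stay unassigned.
assign_nodes_to_bands <- function(centers, bands) {
  o <- order(bands$low_hz)
  lowest <- o[1L]
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    hit <- centers >= bands$low_hz[b] & centers < bands$high_hz[b]
    if (b == lowest) hit <- hit | centers < bands$low_hz[b]
    out[[b]] <- which(hit)
  }
  out
}

#' Map EEG bands to terminal wavelet-packet nodes
#'
#' On the uniform terminal grid of a level-`level` packet tree, node `n`
#' (0-based, frequency order) spans `[n, n+1) * fs / 2^(level+1)` Hz. Each
#' node is assigned to the band containing its center frequency, with two
#' boundary rules: a node centered below the lowest band edge folds into the
#' lowest band (DC and drift go to delta), while nodes centered above the
#' highest band edge (e.g. 100-125 Hz under the default bands at fs = 250)
#' stay unassigned.
#'
#' @param level packet depth.
#' @param fs sampling rate in Hz.
#' @param bands band table.
#' @return named list, one integer vector of 0-based node indices per band.
#' @export
#' @examples
#' band_node_map(7, 250)$alpha  # nodes 8:12, centers ~8.30 .. ~12.21 Hz
band_node_map <- function(level, fs, bands = default_bands()) {
  validate_bands(bands)
  stopifnot(level >= 1L, fs > 0)
  width <- fs / 2^(level + 1)
  centers <- (0:(2^level - 1) + 0.5) * width
  out <- assign_nodes_to_bands(centers, bands)
  for (b in seq_along(out)) {
    if (length(out[[b]]) == 0L) {
      stop(sprintf("band %s captures no wavelet-packet nodes at level %d, fs=%g",
                   names(out)[b], level, fs))
    }
    out[[b]] <- out[[b]] - 1L   # 0-based node indices
  }
  out
}

#' Wavelet subband energy, variance and entropy
#'
#' Decomposes the channel with [wpd()], pools the coefficient vectors of the
#' nodes mapped to each band (assignment by node center frequency, with
#' below-lowest-edge content folded into the lowest band as in
#' [band_node_map()]) into one
#' vector `c`, and computes: energy `sum(c^2)`; Shannon entropy
#' `-sum(p*log(p))` of the normalized coefficient energies
#' `p_j = c_j^2/sum(c^2)` (with `0*log(0) = 0`; the unnormalized literal form
#' `sum(c^2*log(c^2))` is available via `entropy_form = "raw"` in the
#' config); and the sample variance of `c`. An all-zero band has entropy 0.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param config an [run_config()]; uses `bands`, `wavelet_level`,
#'   `wavelet_name`, `wpd_mode`, `entropy_form`.
#' @return named numeric vector with `<band>_energy`, `<band>_variance`,
#'   `<band>_entropy` per band.
#' @export
wavelet_band_features <- function(x, fs, config = run_config()) {
  dec <- wpd(x, level = config$wavelet_level, wavelet = config$wavelet_name,
             fs = fs, mode = config$wpd_mode)
  centers <- dec$node_freqs$center_hz
  bands <- config$bands
  node_map <- assign_nodes_to_bands(centers, bands)
  out <- numeric(0)
  for (b in seq_len(nrow(bands))) {
    in_band <- node_map[[b]]
    if (length(in_band) == 0L) {
      stop(sprintf("band %s captures no wavelet nodes at level %d",
                   bands$name[b], config$wavelet_level))
    }
    cc <- unlist(dec$nodes[in_band], use.names = FALSE)
    pw <- cc^2
    energy <- sum(pw)
    if (config$entropy_form == "shannon") {
      if (energy > 0) {
        p <- pw[pw > 0] / energy
        entropy <- -sum(p * log(p))
      } else {
        entropy <- 0
      }
    } else {
      nz <- pw[pw > 0]
      entropy <- if (length(nz)) sum(nz * log(nz)) else 0
    }
    variance <- if (length(cc) > 1L) stats::var(cc) else 0
    v <- c(energy, variance, entropy)
    names(v) <- paste0(bands$name[b], c("_energy", "_variance", "_entropy"))
    out <- c(out, v)
  }
  out
}
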