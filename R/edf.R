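# Minimal European Data Format (EDF) support: enough to exchange plain
# multichannel EEG with standard tools. EDF is an ASCII fixed-width header
# followed by 16-bit little-endian sample records with per-signal linear
# (physical <-> digital) scaling. Annotations/EDF+ extensions are not
# interpreted.

edf_field <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  trimws(raw)
}

#' Read an EDF file
#'
#' Reads all ordinary signals of an EDF file into a channels x samples
#' matrix, applying the per-signal physical scaling from the header. All
#' signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @return list with `data` (channels x samples numeric matrix), `fs`
#'   (sampling rate in Hz), `channel_labels`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  edf_field(con, 8)                      # version
  edf_field(con, 80)                     # patient id
  edf_field(con, 80)                     # recording id
  edf_field(con, 8); edf_field(con, 8)   # start date, time
  header_bytes <- as.integer(edf_field(con, 8))
  edf_field(con, 44)                     # reserved
  n_records <- as.integer(edf_field(con, 8))
  record_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1L) stop("EDF header: invalid signal count")
  getf <- function(w) vapply(seq_len(ns), function(i) edf_field(con, w),
                             character(1))
  labels    <- getf(16)
  getf(80)                               # transducer
  getf(8)                                # physical dimension
  phys_min  <- as.numeric(getf(8))
  phys_max  <- as.numeric(getf(8))
  dig_min   <- as.numeric(getf(8))
  dig_max   <- as.numeric(getf(8))
  getf(80)                               # prefiltering
  n_samp    <- as.integer(getf(8))
  getf(32)                               # reserved
  if (length(unique(n_samp)) != 1L) {
    stop("EDF signals with differing samples per record are not supported")
  }
  if (is.na(n_records) || n_records < 1L) stop("EDF header: no data records")
  seek(con, header_bytes)
  spr <- n_samp[1L]
  total <- n_records * spr
  data <- matrix(0, nrow = ns, ncol = total)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = ns * spr, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(block) != ns * spr) stop("EDF file truncated at record ", r)
    block <- matrix(block, nrow = spr, ncol = ns)   # signal-major within record
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    data[, cols] <- (t(block) - dig_min) * scale + phys_min
  }
  fs <- spr / record_dur
  list(data = data, fs = fs, channel_labels = labels)
}

#' Write a channels x samples matrix as EDF
#'
#' Writes one EDF file with a single data record holding the whole segment.
#' Samples are quantized to the full 16-bit digital range per channel, so the
#' round-trip error is bounded by (channel amplitude range)/65534.
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz; `fs * ncol(data)` samples span the single
#'   record, whose duration is written as `ncol(data)/fs` seconds.
#' @param path output path.
#' @param channel_labels channel names (<= 16 ASCII chars each).
#' @return the path, invisibly.
#' @export
write_edf <- function(data, fs, path, channel_labels = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), all(is.finite(data)))
  ns <- nrow(data); nsamp <- ncol(data)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(ns))
  }
  stopifnot(length(channel_labels) == ns)
  fmt <- function(x, w) {
    s <- substr(format(x, width = w), 1L, w)
    formatC(s, width = w, flag = "-")
  }
  num8 <- function(x) {
    s <- formatC(x, format = "g", digits = 6, width = 8)
    substr(formatC(trimws(s), width = 8, flag = "-"), 1, 8)
  }
  # physical range per channel; formatted values are re-parsed so the header
  # and the quantization use identical limits
  pmin_s <- character(ns); pmax_s <- character(ns)
  for (i in seq_len(ns)) {
    lo <- min(data[i, ]); hi <- max(data[i, ])
    if (hi <= lo) hi <- lo + 1
    pad <- (hi - lo) * 0.001
    pmin_s[i] <- num8(lo - pad); pmax_s[i] <- num8(hi + pad)
  }
  pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
  dmin <- -32767; dmax <- 32767
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(fmt(s, w), con, nchars = w, eos = NULL)
  put("0", 8)
  put("X X X X", 80)
  put("Startdate 01-JAN-2020 X X X", 80)
  put("01.01.20", 8)
  put("00.00.00", 8)
  put(as.character(header_bytes), 8)
  put("", 44)
  put("1", 8)                               # one data record
  put(num8(nsamp / fs), 8)
  put(as.character(ns), 4)
  for (s in channel_labels) put(s, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(pmin_s[i], 8)
  for (i in seq_len(ns)) put(pmax_s[i], 8)
  for (i in seq_len(ns)) put(as.character(dmin), 8)
  for (i in seq_len(ns)) put(as.character(dmax), 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(as.character(nsamp), 8)
  for (i in seq_len(ns)) put("", 32)
  for (i in seq_len(ns)) {
    dig <- round((data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}
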