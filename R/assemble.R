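#' Extract the full feature vector of one segment
#'
#' Applies all four feature families to every channel and concatenates the
#' results channel-major in the [feature_names()] order: per channel 24
#' time-domain features, 3 FFT features per band, 3 wavelet features per
#' band, and 4 Poincare descriptors per lag. With 22 channels and the
#' default configuration the vector has exactly 1,364 entries
#' (22 x (24 + 15 + 15 + 8)).
#'
#' @param segment an [eeg_segment()].
#' @param config an [run_config()].
#' @return named numeric vector.
#' @export
extract_features <- function(segment, config = run_config()) {
  stopifnot(inherits(segment, "eeg_segment"))
  nms <- feature_names(segment$channel_labels, config)
  out <- numeric(length(nms))
  pos <- 0L
  for (ch in seq_len(nrow(segment$data))) {
    x <- segment$data[ch, ]
    vals <- tryCatch(
      c(temporal_features(x),
        fft_band_features(x, segment$fs, config$bands,
                          window = config$fft_window),
        wavelet_band_features(x, segment$fs, config),
        poincare_features(x, config$poincare_lags)),
      error = function(e) {
        stop(sprintf("channel %s: %s", segment$channel_labels[ch],
                     conditionMessage(e)), call. = FALSE)
      })
    out[(pos + 1L):(pos + length(vals))] <- vals
    pos <- pos + length(vals)
  }
  names(out) <- nms
  out
}

#' Extract the feature matrix of a segment set
#'
#' One row per segment (row order preserves segment order), shared column
#' names, class label per row. Every segment must be labeled.
#'
#' @param set a [segment_set()].
#' @param config an [run_config()].
#' @param channel_labels channel names used to build the header when `set` is
#'   empty (an empty set yields a 0-row matrix with the full header).
#' @param verbose print a progress note every 50 segments.
#' @return A [feature_matrix()].
#' @export
extract_matrix <- function(set, config = run_config(), channel_labels = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(set, "segment_set"))
  n <- length(set$segments)
  if (n == 0L) {
    nms <- feature_names(if (is.null(channel_labels)) character(0) else
      channel_labels, config)
    return(feature_matrix(matrix(numeric(0), nrow = 0, ncol = length(nms),
                                 dimnames = list(NULL, nms)),
                          character(0)))
  }
  labels <- segment_labels(set)
  if (anyNA(labels)) {
    stop("unlabeled segment(s) at position(s): ",
         paste(which(is.na(labels)), collapse = ", "))
  }
  nms <- feature_names(set$segments[[1L]]$channel_labels, config)
  x <- matrix(NA_real_, nrow = n, ncol = length(nms),
              dimnames = list(NULL, nms))
  for (i in seq_len(n)) {
    x[i, ] <- extract_features(set$segments[[i]], config)
    if (verbose && i %% 50L == 0L) {
      message(sprintf("extracted %d / %d segments", i, n))
    }
  }
  feature_matrix(x, labels)
}
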