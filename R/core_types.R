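#' EEG frequency band table
#'
#' The five canonical EEG bands used throughout the pipeline, as half-open
#' intervals `[low_hz, high_hz)` so that adjacent bands never share a DFT bin
#' or a wavelet-packet node.
#'
#' @return A data.frame with columns `name`, `low_hz`, `high_hz` and one row
#'   per band: delta \[0.5, 4), theta \[4, 8), alpha \[8, 13), beta \[13, 30),
#'   gamma \[30, 100).
#' @export
#' @examples
#' default_bands()
default_bands <- function() {
  data.frame(
    name    = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(0.5, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 100),
    stringsAsFactors = FALSE
  )
}

#' Validate a band definition table
#'
#' Checks that a band table has the required columns, that every band has
#' `low_hz < high_hz`, and that bands do not overlap when read as half-open
#' intervals.
#'
#' @param bands data.frame with columns `name`, `low_hz`, `high_hz`.
#' @return The validated band table, invisibly usable in place.
#' @export
validate_bands <- function(bands) {
  if (!is.data.frame(bands) ||
      !all(c("name", "low_hz", "high_hz") %in% names(bands))) {
    stop("bands must be a data.frame with columns name, low_hz, high_hz")
  }
  if (nrow(bands) < 1L) stop("bands must contain at least one band")
  if (anyDuplicated(bands$name)) stop("band names must be unique")
  if (!all(bands$low_hz < bands$high_hz)) {
    bad <- bands$name[bands$low_hz >= bands$high_hz]
    stop("band(s) with low_hz >= high_hz: ", paste(bad, collapse = ", "))
  }
  o <- order(bands$low_hz)
  lo <- bands$low_hz[o]; hi <- bands$high_hz[o]
  if (nrow(bands) > 1L && any(hi[-length(hi)] > lo[-1] + 1e-12)) {
    stop("bands overlap as half-open intervals [low, high)")
  }
  bands
}

#' Construct a single EEG segment
#'
#' An EEG segment is one trial: a channels-by-samples numeric matrix together
#' with its sampling rate, channel labels, and (optionally) a class label and
#' subject identifier. All values must be finite.
#'
#' @param data numeric matrix, channels x samples (amplitude, conventionally
#'   microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names; defaults to
#'   `ch01`, `ch02`, ...
#' @param label class label (single string) or `NA` if unlabeled.
#' @param subject_id subject identifier or `NA`.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, fs, channel_labels = NULL, label = NA_character_,
                        subject_id = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix")
  }
  if (nrow(data) < 1L || ncol(data) < 2L) {
    stop("segment needs >= 1 channel and >= 2 samples per channel")
  }
  if (!all(is.finite(data))) {
    stop("segment contains non-finite values")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length must equal channel count")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         label = as.character(label), subject_id = as.character(subject_id)),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channels x %d samples @ %g Hz",
              nrow(x$data), ncol(x$data), x$fs))
  if (!is.na(x$label)) cat(sprintf("  label=%s", x$label))
  if (!is.na(x$subject_id)) cat(sprintf("  subject=%s", x$subject_id))
  cat("\n")
  invisible(x)
}

#' Construct a segment set
#'
#' A homogeneous ordered collection of [eeg_segment()] objects: all segments
#' must share the sampling rate, channel count and channel order.
#'
#' @param segments list of `eeg_segment`.
#' @param class_names ordered unique class labels; defaults to the unique
#'   labels present, in order of first appearance.
#' @return An object of class `segment_set` with elements `segments` and
#'   `class_names`.
#' @export
segment_set <- function(segments, class_names = NULL) {
  if (!is.list(segments)) stop("segments must be a list of eeg_segment")
  if (length(segments) > 0L) {
    ok <- vapply(segments, inherits, logical(1), what = "eeg_segment")
    if (!all(ok)) stop("all elements must be eeg_segment objects")
    ref <- segments[[1L]]
    for (i in seq_along(segments)) {
      s <- segments[[i]]
      if (!isTRUE(all.equal(s$fs, ref$fs))) {
        stop(sprintf("segment %d: sampling rate %g differs from %g",
                     i, s$fs, ref$fs))
      }
      if (nrow(s$data) != nrow(ref$data)) {
        stop(sprintf("segment %d: %d channels, expected %d",
                     i, nrow(s$data), nrow(ref$data)))
      }
      if (!identical(s$channel_labels, ref$channel_labels)) {
        stop(sprintf("segment %d: channel labels/order differ from segment 1", i))
      }
    }
  }
  labels <- vapply(segments, function(s) s$label, character(1))
  seen <- unique(labels[!is.na(labels)])
  if (is.null(class_names)) {
    class_names <- seen
  } else {
    class_names <- as.character(class_names)
    if (anyDuplicated(class_names)) stop("class_names must be unique")
    if (!all(seen %in% class_names)) {
      stop("segment label(s) not in class_names: ",
           paste(setdiff(seen, class_names), collapse = ", "))
    }
  }
  structure(list(segments = segments, class_names = class_names),
            class = "segment_set")
}

#' @export
length.segment_set <- function(x) length(x$segments)

#' @export
print.segment_set <- function(x, ...) {
  n <- length(x$segments)
  cat(sprintf("<segment_set> %d segments", n))
  if (n > 0L) {
    s <- x$segments[[1L]]
    cat(sprintf(", %d channels x %d samples @ %g Hz",
                nrow(s$data), ncol(s$data), s$fs))
  }
  cat(sprintf("; classes: %s\n", paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Segment labels
#'
#' @param x a `segment_set`.
#' @return character vector of per-segment class labels (`NA` if unlabeled).
#' @export
segment_labels <- function(x) {
  stopifnot(inherits(x, "segment_set"))
  vapply(x$segments, function(s) s$label, character(1))
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline: band table, wavelet settings,
#' Poincare lags, significance level, and cross-validation design.
#'
#' @param bands band table, see [default_bands()].
#' @param wavelet_level wavelet-packet decomposition depth (default 7).
#' @param wavelet_name mother wavelet; only `"haar"` is implemented.
#' @param poincare_lags integer lags for the Poincare descriptors
#'   (default `c(1, 9)`).
#' @param alpha significance level for feature screening (default 0.05).
#' @param cv_folds number of cross-validation folds (default 5).
#' @param cv_repeats number of repeated cross-validation runs (default 10).
#' @param seed root random seed for all stochastic steps.
#' @param fft_window taper applied before the FFT: `"none"` (default) or
#'   `"hann"`.
#' @param wpd_mode `"wpd"` (full wavelet-packet tree, default) or `"dwt"`
#'   (plain dyadic decomposition mapped to bands).
#' @param entropy_form wavelet entropy form: `"shannon"` (default,
#'   `-sum(p*log(p))` on normalized coefficient energies) or `"raw"`
#'   (`sum(c^2*log(c^2))`, the unnormalized literal form, for comparison).
#' @param ttest_variant `"pooled"` (default, Student) or `"welch"`.
#' @param selection_timing `"pre_cv"` (default: screen once on the full data
#'   before cross-validation) or `"per_fold"` (leakage-free: re-screen inside
#'   every training fold).
#' @return An object of class `mi_config`.
#' @export
run_config <- function(bands = default_bands(),
                       wavelet_level = 7L,
                       wavelet_name = "haar",
                       poincare_lags = c(1L, 9L),
                       alpha = 0.05,
                       cv_folds = 5L,
                       cv_repeats = 10L,
                       seed = 1L,
                       fft_window = c("none", "hann"),
                       wpd_mode = c("wpd", "dwt"),
                       entropy_form = c("shannon", "raw"),
                       ttest_variant = c("pooled", "welch"),
                       selection_timing = c("pre_cv", "per_fold")) {
  validate_bands(bands)
  wavelet_level <- as.integer(wavelet_level)
  poincare_lags <- as.integer(poincare_lags)
  cv_folds <- as.integer(cv_folds)
  cv_repeats <- as.integer(cv_repeats)
  if (wavelet_level < 1L) stop("wavelet_level must be >= 1")
  if (length(poincare_lags) < 1L || any(poincare_lags < 1L)) {
    stop("poincare_lags must all be >= 1")
  }
  if (anyDuplicated(poincare_lags)) stop("poincare_lags must be unique")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  if (cv_repeats < 1L) stop("cv_repeats must be >= 1")
  structure(
    list(bands = bands,
         wavelet_level = wavelet_level,
         wavelet_name = match.arg(wavelet_name, "haar"),
         poincare_lags = poincare_lags,
         alpha = alpha,
         cv_folds = cv_folds,
         cv_repeats = cv_repeats,
         seed = as.integer(seed),
         fft_window = match.arg(fft_window),
         wpd_mode = match.arg(wpd_mode),
         entropy_form = match.arg(entropy_form),
         ttest_variant = match.arg(ttest_variant),
         selection_timing = match.arg(selection_timing)),
    class = "mi_config"
  )
}

#' @export
print.mi_config <- function(x, ...) {
  cat("<mi_config>\n")
  cat(sprintf("  bands: %s\n",
              paste(sprintf("%s[%g,%g)", x$bands$name, x$bands$low_hz,
                            x$bands$high_hz), collapse = " ")))
  cat(sprintf("  wavelet: %s, level %d (%s); poincare lags: %s\n",
              x$wavelet_name, x$wavelet_level, x$wpd_mode,
              paste(x$poincare_lags, collapse = ",")))
  cat(sprintf("  alpha=%g; CV %d-fold x %d repeats; seed=%d\n",
              x$alpha, x$cv_folds, x$cv_repeats, x$seed))
  invisible(x)
}

#' Write / read a run configuration as JSON
#'
#' @param config an `mi_config`.
#' @param path file path.
#' @return `read_config` returns an `mi_config`; `write_config` returns the
#'   path invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mi_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(bands = as.data.frame(raw$bands),
             wavelet_level = raw$wavelet_level,
             wavelet_name = raw$wavelet_name,
             poincare_lags = raw$poincare_lags,
             alpha = raw$alpha,
             cv_folds = raw$cv_folds,
             cv_repeats = raw$cv_repeats,
             seed = raw$seed,
             fft_window = raw$fft_window,
             wpd_mode = raw$wpd_mode,
             entropy_form = raw$entropy_form,
             ttest_variant = raw$ttest_variant,
             selection_timing = raw$selection_timing)
}

#' Construct a feature matrix
#'
#' One row per segment, one named column per feature, plus a class label per
#' row. The canonical container passed between extraction, selection and
#' classification.
#'
#' @param x numeric matrix with unique column names.
#' @param labels character vector of per-row class labels (may contain `NA`
#'   for unlabeled rows).
#' @return An object of class `feature_matrix` with elements `x` and `labels`.
#' @export
feature_matrix <- function(x, labels) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (is.null(colnames(x))) stop("x must have column names")
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("one label per row required")
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(factor(x$labels))
  cat(sprintf("<feature_matrix> %d segments x %d features; classes: %s\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s(%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  out <- as.data.frame(x$x)
  out$label <- x$labels
  out
}

# internal: local RNG scope so package functions never disturb the caller's
# random stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# internal: derive a bounded child seed from (root, index) without consuming
# the caller's RNG state
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}
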