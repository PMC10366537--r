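#' Names of the 24 time-domain features, in canonical order
#' @return character vector of length 24.
#' @export
temporal_feature_names <- function() {
  c("min", "max", "mean", "sd", "ieeg", "mav", "ssi", "variance", "rms",
    "wl", "aac", "dasdv", "mode", "kurtosis", "skewness",
    "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
    "q1", "q2", "q3", "zero_crossings", "slope_sign_changes", "range")
}

# internal: per-channel feature names for one family
family_feature_names <- function(family, config) {
  switch(family,
    time = temporal_feature_names(),
    fft = as.vector(t(outer(config$bands$name,
                            c("energy", "variance", "entropy"), paste,
                            sep = "_"))),
    wpd = as.vector(t(outer(config$bands$name,
                            c("energy", "variance", "entropy"), paste,
                            sep = "_"))),
    poincare = as.vector(t(outer(sprintf("lag%d", config$poincare_lags),
                                 c("SD1", "SD2", "SD1xSD2", "SD1dSD2"),
                                 paste, sep = "_"))),
    stop("unknown family: ", family)
  )
}

#' Deterministic feature-name layout
#'
#' The full feature vector is laid out channel-major: all features of the
#' first channel, then the second, and so on. Within a channel the family
#' order is time, fft, wpd, poincare. With 22 channels and the default
#' configuration this yields exactly 1,364 names:
#' 22 x (24 + 3x5 + 3x5 + 4x2).
#'
#' @param channel_labels character vector of unique channel names.
#' @param config an [run_config()] object.
#' @return character vector of unique names of the form
#'   `<channel>__<family>__<feature>`.
#' @export
#' @examples
#' length(feature_names(sprintf("ch%02d", 1:22), run_config()))  # 1364
feature_names <- function(channel_labels, config = run_config()) {
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  per_channel <- unlist(lapply(c("time", "fft", "wpd", "poincare"),
                               function(fam) {
    paste0(fam, "__", family_feature_names(fam, config))
  }), use.names = FALSE)
  unlist(lapply(channel_labels, function(ch) paste0(ch, "__", per_channel)),
         use.names = FALSE)
}

#' Load EEG segments listed in a manifest
#'
#' The manifest is a CSV with columns `file`, `label`, `subject` and, for the
#' matrix format, `fs` (Hz). Each matrix file is a delimited numeric matrix,
#' channels x samples, without a header; for the EDF format, the signal files
#' are EDF and `fs` is taken from the file header. Channel order is taken
#' from the first segment and enforced on all others.
#'
#' @param manifest_path path to the manifest CSV.
#' @param format `"matrix"` or `"edf"`.
#' @param channel_labels optional channel names. For the matrix format these
#'   name the rows in file order; for EDF they select and reorder channels by
#'   label (unknown labels are an error).
#' @return A [segment_set()].
#' @export
load_segments <- function(manifest_path, format = c("matrix", "edf"),
                          channel_labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "label", "subject")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (format == "matrix" && !"fs" %in% names(man)) {
    stop("matrix-format manifest must have an fs column")
  }
  base <- dirname(manifest_path)
  segs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- man$file[i]
    path <- if (file.exists(f)) f else file.path(base, f)
    if (!file.exists(path)) stop("segment file not found: ", f)
    if (format == "matrix") {
      m <- as.matrix(data.table::fread(path, header = FALSE))
      dimnames(m) <- NULL
      storage.mode(m) <- "double"
      if (!all(is.finite(m))) stop("non-finite samples in ", f)
      segs[[i]] <- eeg_segment(m, fs = man$fs[i],
                               channel_labels = channel_labels,
                               label = man$label[i],
                               subject_id = man$subject[i])
    } else {
      edf <- read_edf(path)
      m <- edf$data
      if (!is.null(channel_labels)) {
        missing_ch <- setdiff(channel_labels, edf$channel_labels)
        if (length(missing_ch) > 0L) {
          stop("channel label(s) not in EDF ", f, ": ",
               paste(missing_ch, collapse = ", "))
        }
        m <- m[match(channel_labels, edf$channel_labels), , drop = FALSE]
        labs <- channel_labels
      } else {
        labs <- edf$channel_labels
      }
      if (!all(is.finite(m))) stop("non-finite samples in ", f)
      segs[[i]] <- eeg_segment(m, fs = edf$fs, channel_labels = labs,
                               label = man$label[i],
                               subject_id = man$subject[i])
    }
  }
  segment_set(segs)
}

#' Write a feature matrix as CSV
#'
#' On-disk format: one header row of feature names plus a trailing `label`
#' column; one row per segment. Values are written at full double precision
#' so that a write/read round trip is exact to at least 12 significant
#' digits.
#'
#' @param fm a [feature_matrix()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_table()]
#'
#' @param path CSV path.
#' @param expected_names optional feature-name vector to validate the header
#'   against; any mismatch is a format error.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path, expected_names = NULL) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  if (!"label" %in% names(dt) || names(dt)[ncol(dt)] != "label") {
    stop("feature table must end with a 'label' column")
  }
  feat_names <- setdiff(names(dt), "label")
  if (!is.null(expected_names) && !identical(feat_names, expected_names)) {
    stop("feature table header does not match the expected feature names")
  }
  labels <- as.character(dt[["label"]])
  x <- as.matrix(dt[, feat_names, with = FALSE])
  if (nrow(dt) == 0L) {
    x <- matrix(numeric(0), nrow = 0, ncol = length(feat_names),
                dimnames = list(NULL, feat_names))
    labels <- character(0)
  } else {
    storage.mode(x) <- "double"
  }
  feature_matrix(x, labels)
}

#' Build the study's trial-design manifest
#'
#' Enumerates the trial design of the motor-imagery study the pipeline
#' emulates: each subject performs runs of 48 cued trials, 12 per class over
#' the four classes (left hand, right hand, feet, tongue). With the defaults
#' (9 subjects, 6 runs) this yields 2,592 four-class trials; restricting to
#' the two hand classes yields 1,296.
#'
#' @param n_subjects number of subjects (default 9).
#' @param n_runs runs per subject (default 6).
#' @param trials_per_class trials per class within a run (default 12).
#' @param class_names class labels (default `c("LH","RH","F","T")`).
#' @return data.frame with columns `subject`, `run`, `trial`, `label`; one
#'   row per trial.
#' @export
#' @examples
#' nrow(trial_design())                                  # 2592
#' nrow(subset(trial_design(), label %in% c("LH","RH"))) # 1296
trial_design <- function(n_subjects = 9L, n_runs = 6L,
                         trials_per_class = 12L,
                         class_names = c("LH", "RH", "F", "T")) {
  stopifnot(n_subjects >= 1L, n_runs >= 1L, trials_per_class >= 1L,
            length(class_names) >= 1L)
  per_run <- trials_per_class * length(class_names)
  out <- expand.grid(trial = seq_len(per_run), run = seq_len(n_runs),
                     subject = sprintf("S%02d", seq_len(n_subjects)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$label <- rep(rep(class_names, each = trials_per_class),
                   times = n_runs * n_subjects)
  out[, c("subject", "run", "trial", "label")]
}
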