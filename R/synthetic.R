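# Class-conditioned synthetic EEG. Each channel is a 1/f^gamma background
# plus one band-limited random-phase oscillation per EEG band (filtered white
# noise, so within-band variance and entropy behave realistically). The class
# effect is event-related-desynchronization-like: on a class's affected
# channels the affected band's amplitude is scaled by (1 - effect_size).

#' Default 22-channel motor-imagery montage labels
#'
#' Central/centro-parietal 10-20 montage labels matching the 22-electrode
#' layout common in motor-imagery recordings.
#' @return character vector of 22 labels.
#' @export
mi_montage_22 <- function() {
  c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP3", "CP1", "CPz", "CP2", "CP4",
    "P1", "Pz", "P2", "POz")
}

#' Parameters of the synthetic EEG generator
#'
#' @param n_channels number of channels (default 22).
#' @param fs sampling rate in Hz (default 250).
#' @param duration_s segment duration in seconds (default 3; `fs*duration_s`
#'   must be an integer).
#' @param n_per_class segments per class.
#' @param class_names class labels (default left hand, right hand, feet,
#'   tongue).
#' @param effect_size relative amplitude attenuation depth `delta` in
#'   \[0, 1\] applied to the affected band on a class's affected channels
#'   (default 0.8).
#' @param affected_channels named list mapping each class to the channel
#'   indices carrying its effect. The default assigns disjoint sensorimotor
#'   triplets (contralateral hand areas, midline for feet, lateral for
#'   tongue).
#' @param affected_band name of the modulated band (default `"alpha"`).
#' @param noise_exponent spectral slope gamma of the 1/f^gamma background
#'   (default 1).
#' @param band_amplitudes named numeric vector of per-band oscillation
#'   amplitudes (relative units); the default profile is alpha/delta
#'   dominant, mimicking resting sensorimotor EEG.
#' @param noise_amplitude background amplitude in the same relative units.
#' @param base_scale overall scale factor converting relative units to
#'   microvolt-like amplitudes (default 10).
#' @param seed root seed; every segment draws from a substream derived from
#'   (seed, segment index), so datasets are reproducible under any
#'   generation order.
#' @param bands band table (default [default_bands()]).
#' @return object of class `synth_params`.
#' @export
synth_params <- function(n_channels = 22L, fs = 250, duration_s = 3,
                         n_per_class = 10L,
                         class_names = c("LH", "RH", "F", "T"),
                         effect_size = 0.8,
                         affected_channels = NULL,
                         affected_band = "alpha",
                         noise_exponent = 1,
                         band_amplitudes = c(delta = 2.0, theta = 1.2,
                                             alpha = 2.0, beta = 0.8,
                                             gamma = 0.4),
                         noise_amplitude = 1.0,
                         base_scale = 10,
                         seed = 1L,
                         bands = default_bands()) {
  n_channels <- as.integer(n_channels)
  n_per_class <- as.integer(n_per_class)
  validate_bands(bands)
  n_samples <- fs * duration_s
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("duration_s * fs must be an integer number of samples")
  }
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (effect_size < 0 || effect_size > 1) stop("effect_size must be in [0, 1]")
  if (!affected_band %in% bands$name) {
    stop("affected_band must be one of: ", paste(bands$name, collapse = ", "))
  }
  if (!all(bands$name %in% names(band_amplitudes))) {
    stop("band_amplitudes must name every band")
  }
  if (is.null(affected_channels)) {
    defaults <- list(LH = c(6L, 12L, 18L), RH = c(2L, 8L, 14L),
                     F = c(4L, 10L, 16L), T = c(7L, 13L, 19L))
    affected_channels <- lapply(seq_along(class_names), function(i) {
      if (n_channels == 22L && class_names[i] %in% names(defaults)) {
        defaults[[class_names[i]]]
      } else {
        # spread classes over whatever montage is available
        (((i - 1L) * max(1L, n_channels %/% length(class_names))) %%
           n_channels) + 1L
      }
    })
    names(affected_channels) <- class_names
  }
  if (!all(class_names %in% names(affected_channels))) {
    stop("affected_channels must name every class")
  }
  for (cl in class_names) {
    idx <- affected_channels[[cl]]
    if (any(idx < 1L | idx > n_channels)) {
      stop("affected channel index out of range for class ", cl)
    }
  }
  structure(list(n_channels = n_channels, fs = fs, duration_s = duration_s,
                 n_per_class = n_per_class, class_names = class_names,
                 effect_size = effect_size,
                 affected_channels = affected_channels[class_names],
                 affected_band = affected_band,
                 noise_exponent = noise_exponent,
                 band_amplitudes = band_amplitudes,
                 noise_amplitude = noise_amplitude,
                 base_scale = base_scale,
                 seed = as.integer(seed), bands = bands),
            class = "synth_params")
}

# internal: band-limited unit-variance noise via FFT masking
bandlimited_noise <- function(n, fs, low_hz, high_hz) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freq <- (0:(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)            # two-sided -> folded frequency
  keep <- freq >= low_hz & freq < high_hz
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# internal: 1/f^gamma background, unit variance
pink_noise <- function(n, fs, gamma) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freq <- (0:(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)
  shape <- ifelse(freq > 0, freq^(-gamma / 2), 0)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# internal: one synthetic segment for a given class
synth_segment <- function(params, class_name, seg_seed) {
  n <- as.integer(round(params$fs * params$duration_s))
  labs <- if (params$n_channels == 22L) mi_montage_22() else
    sprintf("ch%02d", seq_len(params$n_channels))
  affected <- params$affected_channels[[class_name]]
  data <- with_seed(seg_seed, {
    m <- matrix(0, nrow = params$n_channels, ncol = n)
    for (ch in seq_len(params$n_channels)) {
      x <- params$noise_amplitude *
        pink_noise(n, params$fs, params$noise_exponent)
      for (b in seq_len(nrow(params$bands))) {
        bn <- params$bands$name[b]
        amp <- params$band_amplitudes[[bn]]
        if (bn == params$affected_band && ch %in% affected) {
          amp <- amp * (1 - params$effect_size)
        }
        x <- x + amp * bandlimited_noise(n, params$fs,
                                         params$bands$low_hz[b],
                                         params$bands$high_hz[b])
      }
      m[ch, ] <- params$base_scale * x
    }
    m
  })
  eeg_segment(data, fs = params$fs, channel_labels = labs,
              label = class_name, subject_id = "synthetic")
}

#' Generate a class-conditioned synthetic EEG dataset
#'
#' Produces `n_per_class * length(class_names)` segments (class-blocked
#' order). Each channel is 1/f background plus per-band random-phase
#' oscillations; on a class's affected channels the affected band's amplitude
#' is scaled by `(1 - effect_size)`. Deterministic given the seed.
#'
#' @param params a [synth_params()] object.
#' @return A [segment_set()].
#' @export
#' @examples
#' set <- generate_dataset(synth_params(n_per_class = 2, seed = 7))
#' length(set)  # 8
generate_dataset <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  idx <- 0L
  segs <- list()
  for (cl in params$class_names) {
    for (r in seq_len(params$n_per_class)) {
      idx <- idx + 1L
      segs[[idx]] <- synth_segment(params, cl, child_seed(params$seed, idx))
    }
  }
  segment_set(segs, class_names = params$class_names)
}

#' Generate a null dataset (labels carry no signal)
#'
#' Identical generative process with `effect_size` forced to 0: class labels
#' are assigned but every class is drawn from the same distribution. With the
#' same seed, `generate_dataset` under `effect_size = 0` returns an identical
#' dataset.
#'
#' @param params a [synth_params()] object (its `effect_size` is ignored).
#' @return A [segment_set()].
#' @export
generate_null_dataset <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  params$effect_size <- 0
  generate_dataset(params)
}

#' Write a segment set as matrix files plus a manifest
#'
#' Emits one headerless CSV (channels x samples) per segment and a
#' `manifest.csv` with columns `file`, `label`, `subject`, `fs`, consumable
#' by [load_segments()].
#'
#' @param set a [segment_set()].
#' @param dir output directory (created if missing).
#' @return path to the manifest, invisibly.
#' @export
write_dataset <- function(set, dir) {
  stopifnot(inherits(set, "segment_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(set$segments)
  files <- sprintf("segment_%04d.csv", seq_len(n))
  for (i in seq_len(n)) {
    s <- set$segments[[i]]
    data.table::fwrite(as.data.frame(s$data), file.path(dir, files[i]),
                       col.names = FALSE)
  }
  man <- data.frame(
    file = files,
    label = vapply(set$segments, function(s) s$label, character(1)),
    subject = vapply(set$segments, function(s) s$subject_id, character(1)),
    fs = vapply(set$segments, function(s) s$fs, numeric(1))
  )
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}
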