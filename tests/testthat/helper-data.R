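# shared fixtures, built in code

# pure tone sampled at fs
tone <- function(freq, fs = 250, n = 750, amp = 1) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / fs)
}

# small deterministic segment set: n segments of white noise with given labels
tiny_segment_set <- function(labels, n_channels = 3L, n_samples = 256L,
                             fs = 250, seed = 11L) {
  segs <- lapply(seq_along(labels), function(i) {
    set.seed(seed + i)
    eeg_segment(matrix(rnorm(n_channels * n_samples), n_channels),
                fs = fs, label = labels[i], subject_id = "S01")
  })
  segment_set(segs)
}

# well-separated 2-class Gaussian clouds for classifier tests
gaussian_clouds <- function(n_per_class = 50L, p = 10L, sep = 4,
                            classes = c("a", "b"), seed = 5L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, mean = sep / sqrt(p)), n_per_class))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(classes, each = n_per_class))
}
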