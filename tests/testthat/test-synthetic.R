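test_that("generator honours shape, determinism and parameter validation", {
  p <- synth_params(n_per_class = 10, seed = 1)
  set <- generate_dataset(p)
  expect_length(set, 40L)
  expect_identical(dim(set$segments[[1]]$data), c(22L, 750L))
  expect_identical(set$segments[[1]]$channel_labels, mi_montage_22())
  expect_identical(table(segment_labels(set)),
                   table(rep(c("LH", "RH", "F", "T"), each = 10)))

  set2 <- generate_dataset(p)
  expect_identical(set$segments[[7]]$data, set2$segments[[7]]$data)
  set3 <- generate_dataset(synth_params(n_per_class = 10, seed = 2))
  expect_false(identical(set$segments[[7]]$data, set3$segments[[7]]$data))

  expect_error(synth_params(effect_size = 1.5), "effect_size")
  expect_error(synth_params(duration_s = 1 / 3), "integer number of samples")
  expect_error(synth_params(affected_channels = list(LH = 99, RH = 1, F = 2,
                                                     T = 3)), "out of range")
  tiny <- generate_dataset(synth_params(n_per_class = 1, seed = 9))
  expect_length(tiny, 4L)
})

test_that("effect size attenuates alpha energy on affected channels", {
  # alpha-band FFT energy on an LH-affected channel, LH vs RH segments
  p <- synth_params(n_per_class = 40, class_names = c("LH", "RH"),
                    effect_size = 0.8, seed = 1)
  set <- generate_dataset(p)
  labs <- segment_labels(set)
  ch <- p$affected_channels$LH[1]
  e <- vapply(set$segments, function(s) {
    fft_band_features(s$data[ch, ], s$fs)[["alpha_energy"]]
  }, numeric(1))
  expect_lt(mean(e[labs == "LH"]), mean(e[labs == "RH"]))
  expect_lt(t.test(e[labs == "LH"], e[labs == "RH"])$p.value, 1e-3)
})

test_that("the null generator removes the class effect entirely", {
  p <- synth_params(n_per_class = 5, seed = 21)
  null1 <- generate_null_dataset(p)
  p0 <- synth_params(n_per_class = 5, effect_size = 0, seed = 21)
  null2 <- generate_dataset(p0)
  for (i in seq_along(null1$segments)) {
    expect_identical(null1$segments[[i]]$data, null2$segments[[i]]$data)
  }
})

test_that("null classes are statistically indistinguishable", {
  # under the null, the same feature computed for two different labels has
  # the same distribution
  p <- synth_params(n_per_class = 40, class_names = c("LH", "RH"), seed = 1)
  set <- generate_null_dataset(p)
  labs <- segment_labels(set)
  ch <- p$affected_channels$LH[1]
  e <- vapply(set$segments, function(s) {
    fft_band_features(s$data[ch, ], s$fs)[["alpha_energy"]]
  }, numeric(1))
  expect_gt(suppressWarnings(
    ks.test(e[labs == "LH"], e[labs == "RH"])$p.value), 0.01)
  s <- vapply(set$segments, function(x) sd(x$data[ch, ]), numeric(1))
  expect_gt(suppressWarnings(
    ks.test(s[labs == "LH"], s[labs == "RH"])$p.value), 0.01)
})

test_that("background spectrum falls with frequency (1/f-like)", {
  p <- synth_params(n_per_class = 6, class_names = "X",
                    affected_channels = list(X = 1L), seed = 13)
  set <- generate_dataset(p)
  # mean power in a low vs high out-of-oscillation comparison: delta+theta
  # bands should carry far more power than gamma at the default profile
  pw <- rowMeans(vapply(set$segments, function(s) {
    f <- fft_band_features(s$data[2, ], s$fs)
    c(f[["delta_energy"]], f[["gamma_energy"]])
  }, numeric(2)))
  expect_gt(pw[1], pw[2])
})

test_that("written datasets reload identically through the manifest", {
  dir <- withr::local_tempdir()
  p <- synth_params(n_channels = 4, n_per_class = 2, seed = 3)
  set <- generate_dataset(p)
  man <- write_dataset(set, dir)
  back <- load_segments(man, "matrix",
                        channel_labels = set$segments[[1]]$channel_labels)
  expect_length(back, length(set))
  expect_identical(segment_labels(back), segment_labels(set))
  expect_equal(back$segments[[3]]$data, set$segments[[3]]$data,
               tolerance = 1e-12, ignore_attr = TRUE)
})
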