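test_that("feature name layout matches the channel x family architecture", {
  cfg <- run_config()
  nms22 <- feature_names(sprintf("ch%02d", 1:22), cfg)
  expect_length(nms22, 1364L)
  expect_false(anyDuplicated(nms22) > 0)

  nms1 <- feature_names("Cz", cfg)
  expect_length(nms1, 62L)  # 24 + 15 + 15 + 8
  # channel-major, family order time, fft, wpd, poincare
  expect_identical(nms1[1], "Cz__time__min")
  expect_identical(nms1[25], "Cz__fft__delta_energy")
  expect_identical(nms1[40], "Cz__wpd__delta_energy")
  expect_identical(nms1[55], "Cz__poincare__lag1_SD1")
  expect_identical(nms22[63], "ch02__time__min")

  cfg1 <- run_config(poincare_lags = 1L)
  expect_length(feature_names(sprintf("ch%02d", 1:22), cfg1), 1276L)

  expect_error(feature_names(c("a", "a"), cfg), "duplicate")
})

test_that("name layout is a pure function of labels and config", {
  cfg <- run_config()
  expect_identical(feature_names(c("C3", "Cz", "C4"), cfg),
                   feature_names(c("C3", "Cz", "C4"), cfg))
  # channel order drives block order
  a <- feature_names(c("C3", "C4"), cfg)
  b <- feature_names(c("C4", "C3"), cfg)
  expect_identical(sort(a), sort(b))
  expect_false(identical(a, b))
})

test_that("matrix-format manifest loading honours the contract", {
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    m <- matrix(rnorm(22 * 750), 22)
    data.table::fwrite(as.data.frame(m), file.path(dir, sprintf("s%d.csv", i)),
                       col.names = FALSE)
  }
  man <- data.frame(file = sprintf("s%d.csv", 1:3),
                    label = c("LH", "RH", "LH"),
                    subject = "S01", fs = 250)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)

  set <- load_segments(file.path(dir, "manifest.csv"), "matrix")
  expect_s3_class(set, "segment_set")
  expect_length(set, 3L)
  expect_identical(set$class_names, c("LH", "RH"))
  expect_identical(dim(set$segments[[1]]$data), c(22L, 750L))

  # missing file
  man_bad <- man; man_bad$file[2] <- "nope.csv"
  write.csv(man_bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(load_segments(file.path(dir, "bad.csv"), "matrix"), "nope.csv")

  # inconsistent channel counts
  data.table::fwrite(as.data.frame(matrix(rnorm(21 * 750), 21)),
                     file.path(dir, "s2.csv"), col.names = FALSE)
  expect_error(load_segments(file.path(dir, "manifest.csv"), "matrix"),
               "channels")

  # non-finite samples
  m <- matrix(rnorm(22 * 750), 22); m[3, 5] <- NA
  data.table::fwrite(as.data.frame(m), file.path(dir, "s2.csv"),
                     col.names = FALSE)
  expect_error(load_segments(file.path(dir, "manifest.csv"), "matrix"),
               "non-finite")
})

test_that("feature tables round-trip through CSV", {
  set.seed(42)
  nms <- feature_names(c("C3", "Cz"), run_config())
  x <- matrix(rnorm(3 * length(nms)) * 10^sample(-3:3, 3 * length(nms),
                                                 replace = TRUE),
              nrow = 3, dimnames = list(NULL, nms))
  fm <- feature_matrix(x, c("LH", "RH", "LH"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fm, path)
  back <- read_feature_table(path, expected_names = nms)
  expect_identical(colnames(back$x), nms)
  expect_identical(back$labels, fm$labels)
  expect_equal(back$x, fm$x, tolerance = 1e-12)

  # empty matrix: header-only file, 0 rows back
  fm0 <- feature_matrix(x[0, , drop = FALSE], character(0))
  write_feature_table(fm0, path)
  back0 <- read_feature_table(path)
  expect_identical(nrow(back0$x), 0L)
  expect_identical(colnames(back0$x), nms)

  # renamed column is a format error
  txt <- readLines(path)
  txt[1] <- sub("C3__time__min", "C3__time__minimum", txt[1], fixed = TRUE)
  writeLines(txt, path)
  expect_error(read_feature_table(path, expected_names = nms),
               "does not match")
})

test_that("run_config validates its invariants and round-trips as JSON", {
  expect_error(run_config(wavelet_level = 0), "wavelet_level")
  expect_error(run_config(poincare_lags = c(0, 9)), "lags")
  expect_error(run_config(alpha = 0), "alpha")
  expect_error(run_config(alpha = 1), "alpha")
  expect_error(run_config(cv_folds = 1), "cv_folds")
  expect_error(run_config(cv_repeats = 0), "cv_repeats")
  bad_bands <- default_bands(); bad_bands$high_hz[1] <- 0.2
  expect_error(run_config(bands = bad_bands), "low_hz >= high_hz")

  cfg <- run_config(wavelet_level = 6, poincare_lags = c(2, 5), alpha = 0.01,
                    seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg)
})

test_that("segment and set constructors reject malformed input", {
  expect_error(eeg_segment(matrix(1:4, 2), fs = 0), "fs")
  expect_error(eeg_segment(matrix(c(1, NA, 3, 4), 2), fs = 250), "non-finite")
  expect_error(eeg_segment(matrix(1, 1, 1), fs = 250), "2 samples")
  s1 <- eeg_segment(matrix(rnorm(20), 2), fs = 250, label = "LH")
  s2 <- eeg_segment(matrix(rnorm(20), 2), fs = 128, label = "RH")
  expect_error(segment_set(list(s1, s2)), "sampling rate")
  s3 <- eeg_segment(matrix(rnorm(30), 3), fs = 250)
  expect_error(segment_set(list(s1, s3)), "channels")
  expect_error(segment_set(list(s1), class_names = "RH"), "not in class_names")
})

test_that("trial design enumerates the study's sample counts", {
  td <- trial_design()
  expect_identical(nrow(td), 2592L)
  expect_identical(nrow(td[td$label %in% c("LH", "RH"), ]), 1296L)
  expect_true(all(table(td$label) == 648L))
  # 12 per class within every subject x run cell
  cell <- td[td$subject == "S01" & td$run == 1, ]
  expect_true(all(table(cell$label) == 12L))
})
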