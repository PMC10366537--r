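test_that("hand-checkable signals give the expected temporal features", {
  f <- temporal_features(c(1, 2, 3))
  expect_equal(f[["mean"]], 2)
  expect_equal(f[["sd"]], 1)
  expect_equal(f[["variance"]], 1)
  expect_equal(f[["range"]], 2)
  expect_equal(f[["wl"]], 2)
  expect_equal(f[["aac"]], 1)
  expect_equal(f[["zero_crossings"]], 0)
  expect_equal(f[["slope_sign_changes"]], 0)
  expect_equal(f[["ieeg"]], 6)
  expect_equal(f[["mav"]], 2)
  expect_equal(f[["ssi"]], 14)
  expect_equal(f[["rms"]], sqrt(14 / 3))
  expect_equal(f[["dasdv"]], 1)

  g <- temporal_features(c(1, -1, 1, -1))
  expect_equal(g[["zero_crossings"]], 3)
  expect_equal(g[["slope_sign_changes"]], 2)
  expect_equal(g[["mav"]], 1)
  expect_equal(g[["rms"]], 1)
  expect_equal(g[["min"]], -1)
  expect_equal(g[["max"]], 1)
})

test_that("internal identities hold on every input", {
  set.seed(3)
  for (x in list(rnorm(100), tone(5, n = 200), cumsum(rnorm(500)))) {
    f <- temporal_features(x)
    expect_true(f[["min"]] <= f[["q1"]] && f[["q1"]] <= f[["q2"]] &&
                  f[["q2"]] <= f[["q3"]] && f[["q3"]] <= f[["max"]])
    expect_equal(f[["range"]], f[["max"]] - f[["min"]])
    expect_equal(f[["variance"]], f[["sd"]]^2)
    expect_equal(f[["hjorth_activity"]], f[["variance"]])
    expect_equal(f[["ieeg"]], length(x) * f[["mav"]])
    expect_true(all(f[c("ssi", "ieeg", "mav", "rms", "wl", "aac",
                        "dasdv")] >= 0))
    expect_true(f[["zero_crossings"]] == round(f[["zero_crossings"]]))
    expect_true(all(is.finite(f)))
  }
})

test_that("hjorth mobility agrees with the brute-force variance ratio", {
  x <- tone(5, fs = 250, n = 200)
  h <- hjorth(x)
  # independent route: direct variance ratios of difference series
  mob <- sqrt(var(diff(x)) / var(x))
  cplx <- sqrt(var(diff(diff(x))) / var(diff(x))) / mob
  expect_equal(h[["mobility"]], mob, tolerance = 1e-12)
  expect_equal(h[["complexity"]], cplx, tolerance = 1e-12)

  y <- c(0, 1, 0, -1, 0, 1, 0, -1)
  hy <- hjorth(y)
  expect_equal(hy[["activity"]], var(y), tolerance = 1e-12)
  expect_equal(hy[["mobility"]], sqrt(var(diff(y)) / var(y)),
               tolerance = 1e-12)

  expect_identical(hjorth(rep(3, 10)),
                   c(activity = 0, mobility = 0, complexity = 0))
})

test_that("scale equivariance and shift invariance hold", {
  set.seed(9)
  x <- rnorm(300)
  f <- temporal_features(x)
  fc <- temporal_features(3 * x)
  for (nm in c("min", "max", "mean", "sd", "rms", "q1", "q2", "q3", "range",
               "mav", "ieeg", "wl", "aac", "dasdv")) {
    expect_equal(fc[[nm]], 3 * f[[nm]], tolerance = 1e-10, label = nm)
  }
  expect_equal(fc[["ssi"]], 9 * f[["ssi"]], tolerance = 1e-10)
  expect_equal(fc[["variance"]], 9 * f[["variance"]], tolerance = 1e-10)
  for (nm in c("kurtosis", "skewness", "hjorth_mobility",
               "hjorth_complexity", "zero_crossings",
               "slope_sign_changes")) {
    expect_equal(fc[[nm]], f[[nm]], tolerance = 1e-10, label = nm)
  }
  fs <- temporal_features(x + 100)
  for (nm in c("sd", "variance", "wl", "aac", "dasdv", "kurtosis",
               "skewness", "hjorth_mobility", "hjorth_complexity",
               "slope_sign_changes")) {
    expect_equal(fs[[nm]], f[[nm]], tolerance = 1e-8, label = nm)
  }
})

test_that("degenerate inputs follow the stated conventions", {
  expect_error(temporal_features(c(1, 2)), "3 samples")
  const <- temporal_features(rep(2, 50))
  expect_equal(const[["hjorth_mobility"]], 0)
  expect_equal(const[["hjorth_complexity"]], 0)
  expect_equal(const[["mode"]], 2)
  expect_true(all(is.finite(const)))
  # mode: rounding to 2 decimals, ties broken toward the smallest value
  expect_equal(temporal_features(c(1.004, 1.001, 2.002, 2.001, 5))[["mode"]],
               1)
})
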