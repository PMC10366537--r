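test_that("orthonormal Haar analysis of a pair is exact", {
  w <- wpd(c(1, 3), level = 1, fs = 2)
  expect_equal(w$nodes[[1]], 4 / sqrt(2))   # approximation 2*sqrt(2)
  expect_equal(w$nodes[[2]], 2 / sqrt(2))   # detail sqrt(2)
  expect_equal(sum(unlist(w$nodes)^2), 1^2 + 3^2)  # 8 + 2 = 10
})

test_that("decomposition length preconditions are enforced", {
  x <- rnorm(750)
  expect_s3_class(wpd(x, 7, fs = 250), "wpd_decomposition")
  expect_error(wpd(x, 10, fs = 250), "shorter than 2\\^level")
})

test_that("total terminal energy equals signal energy (orthonormality)", {
  set.seed(31)
  for (len in c(128, 256, 1024)) {
    x <- rnorm(len)
    w <- wpd(x, 7, fs = 250)
    expect_equal(sum(unlist(w$nodes)^2), sum(x^2), tolerance = 1e-6)
  }
})

test_that("frequency ordering localizes tones at node centers", {
  width <- 125 / 128
  t <- (0:1023) / 250
  for (n in c(0L, 3L, 9L, 17L, 40L, 77L, 101L, 120L)) {
    f <- (n + 0.5) * width
    w <- wpd(sin(2 * pi * f * t), level = 7, fs = 250)
    energies <- vapply(w$nodes, function(v) sum(v^2), numeric(1))
    expect_identical(which.max(energies) - 1L, n,
                     label = sprintf("tone at %.3f Hz", f))
  }
})

test_that("band-to-node map follows the center-frequency rule", {
  bm <- band_node_map(7, 250)
  expect_identical(bm$alpha, 8:12)    # centers ~8.30 .. ~12.21 Hz
  expect_identical(bm$delta, 0:3)     # node 0 folds down into delta
  expect_identical(bm$theta, 4:7)
  # nodes centered above 100 Hz stay unassigned
  assigned <- unlist(bm)
  expect_false(anyDuplicated(assigned) > 0)
  centers <- (setdiff(0:127, assigned) + 0.5) * 125 / 128
  expect_true(all(centers >= 100))
  # bands tiling [0, fs/2) capture every node exactly once
  tiling <- data.frame(name = c("lo", "hi"), low_hz = c(0, 60),
                       high_hz = c(60, 125))
  bm2 <- band_node_map(7, 250, tiling)
  expect_identical(sort(unname(unlist(bm2))), 0:127)
  # a band narrower than the node resolution errors by name (the lowest band
  # can never be empty because sub-band content folds down into it)
  nb <- data.frame(name = c("lo", "sliver"), low_hz = c(0, 8.0),
                   high_hz = c(8.0, 8.1))
  expect_error(band_node_map(7, 250, nb), "sliver")
})

test_that("wavelet band features behave on archetypal signals", {
  cfg <- run_config()
  # constant signal: all energy in the node containing DC -> delta
  const <- wavelet_band_features(rep(2, 768), 250, cfg)
  expect_equal(const[["delta_energy"]], sum(rep(2, 768)^2), tolerance = 1e-9)
  for (b in c("theta", "alpha", "beta", "gamma")) {
    expect_lt(const[[paste0(b, "_energy")]], 1e-18)
  }
  # 10 Hz tone: alpha dominates
  w <- wavelet_band_features(tone(10, n = 768), 250, cfg)
  en <- w[grep("_energy$", names(w))]
  expect_identical(names(which.max(en)), "alpha_energy")
  # amplitude scaling: energy and variance x4, entropy unchanged
  set.seed(17)
  x <- rnorm(768)
  w1 <- wavelet_band_features(x, 250, cfg)
  w2 <- wavelet_band_features(2 * x, 250, cfg)
  for (b in default_bands()$name) {
    expect_equal(w2[[paste0(b, "_energy")]], 4 * w1[[paste0(b, "_energy")]],
                 tolerance = 1e-9)
    expect_equal(w2[[paste0(b, "_variance")]],
                 4 * w1[[paste0(b, "_variance")]], tolerance = 1e-9)
    expect_equal(w2[[paste0(b, "_entropy")]], w1[[paste0(b, "_entropy")]],
                 tolerance = 1e-9)
  }
})

test_that("entropy is bounded by log of the in-band coefficient count", {
  cfg <- run_config()
  bm <- band_node_map(7, 250)
  set.seed(23)
  w <- wavelet_band_features(rnorm(768), 250, cfg)
  coef_per_node <- 768 / 128
  for (b in names(bm)) {
    expect_lte(w[[paste0(b, "_entropy")]],
               log(length(bm[[b]]) * coef_per_node) + 1e-9)
    expect_gte(w[[paste0(b, "_entropy")]], 0)
  }
})

test_that("FFT and WPD alpha energies agree in rank across segments", {
  set.seed(41)
  n <- 768
  amps <- runif(100, 0.2, 5)
  fft_e <- numeric(100); wpd_e <- numeric(100)
  cfg <- run_config()
  for (i in 1:100) {
    x <- rnorm(n) + amps[i] * tone(10.5, n = n)
    fft_e[i] <- fft_band_features(x, 250)[["alpha_energy"]]
    wpd_e[i] <- wavelet_band_features(x, 250, cfg)[["alpha_energy"]]
  }
  expect_gt(cor(fft_e, wpd_e, method = "spearman"), 0.9)
})

test_that("dwt mode yields dyadic subbands with conserved energy", {
  set.seed(5)
  x <- rnorm(256)
  w <- wpd(x, 4, fs = 256, mode = "dwt")
  expect_length(w$nodes, 5L)
  expect_equal(sum(unlist(w$nodes)^2), sum(x^2), tolerance = 1e-9)
  expect_equal(w$node_freqs$high_hz, c(8, 16, 32, 64, 128))
})
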