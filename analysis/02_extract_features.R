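#!/usr/bin/env Rscript
# Step 2: extract the 1,364-dimensional feature matrices.
#
# For every segment of both datasets: 24 time-domain features, 15 FFT
# subband features (energy/variance/entropy x 5 bands), 15 wavelet-packet
# subband features, and 8 Poincare descriptors (SD1, SD2, product, ratio at
# lags 1 and 9) per channel, channel-major. Feature tables are multi-MB CSVs
# and live under scratch/.

suppressMessages(library(mieeg))

cfg <- run_config()
root <- "scratch/analysis"

for (name in c("signal", "null")) {
  man <- file.path(root, name, "manifest.csv")
  set <- load_segments(man, "matrix", channel_labels = mi_montage_22())
  fm <- extract_matrix(set, cfg, verbose = TRUE)
  fam <- vapply(strsplit(colnames(fm$x), "__", fixed = TRUE), `[`,
                character(1), 2L)
  out <- file.path(root, sprintf("features_%s.csv", name))
  write_feature_table(fm, out)
  cat(sprintf("%s: %d x %d features (time %d, fft %d, wpd %d, poincare %d) -> %s\n",
              name, nrow(fm$x), ncol(fm$x), sum(fam == "time"),
              sum(fam == "fft"), sum(fam == "wpd"), sum(fam == "poincare"),
              out))
}
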