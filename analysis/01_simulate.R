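#!/usr/bin/env Rscript
# Step 1: simulate the study's two datasets.
#
# Two synthetic EEG datasets stand in for the motor-imagery recordings:
#   - "signal": two classes (left hand / right hand), 100 segments per class,
#     with a strong (effect_size = 0.9) alpha-band desynchronization on each
#     class's sensorimotor channels;
#   - "null": all four classes (LH/RH/F/T), 25 segments per class, with the
#     class effect switched off -- labels carry no information.
# Segments are 22 channels x 3 s at 250 Hz. Raw segment matrices are bulky,
# so they are written under scratch/ (not part of the deliverable); later
# steps reload them through their manifests.

suppressMessages(library(mieeg))

seed <- 1L
out_root <- "scratch/analysis"

sig_params <- synth_params(n_per_class = 100L, class_names = c("LH", "RH"),
                           effect_size = 0.9, seed = seed)
sig <- generate_dataset(sig_params)
man_sig <- write_dataset(sig, file.path(out_root, "signal"))
cat(sprintf("signal dataset: %d segments (%s) -> %s\n", length(sig),
            paste(sig$class_names, collapse = "/"), man_sig))

null_params <- synth_params(n_per_class = 25L, seed = seed)
nul <- generate_null_dataset(null_params)
man_null <- write_dataset(nul, file.path(out_root, "null"))
cat(sprintf("null dataset:   %d segments (%s) -> %s\n", length(nul),
            paste(nul$class_names, collapse = "/"), man_null))

# the trial design the real study would enumerate
td <- trial_design()
cat(sprintf("trial design: %d four-class trials, %d two-class (LH/RH)\n",
            nrow(td), sum(td$label %in% c("LH", "RH"))))
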