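#!/usr/bin/env Rscript
# Generate the synthetic study dataset: two conditions ("control" and
# "induced") differing only in puncta load per cell, three images each,
# plus a tandem-reporter condition with a known autolysosome fraction.
# Everything downstream (02-05) consumes the files this writes.

suppressPackageStartupMessages(library(punctaflux))

out <- "results/dataset"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- validate_config(list(
  mode = "simulate", seed = 20260930, out_dir = out, n_images = 3,
  synthetic = list(
    control = list(n_nuclei = 12, n_border_nuclei = 2,
                   puncta_per_cell_mean = 5),
    induced = list(n_nuclei = 12, n_border_nuclei = 2,
                   puncta_per_cell_mean = 10),
    tandem = list(n_nuclei = 12, n_border_nuclei = 0,
                  puncta_per_cell_mean = 10, autolysosome_fraction = 0.4))))
rep <- run_pipeline(cfg)

message(sprintf("wrote %d images (3 conditions x 3) to %s", rep$n_images, out))
message(sprintf("ground truth: %d nuclei rows, %d puncta rows",
                nrow(read.csv(file.path(out, "truth_nuclei.csv"))),
                nrow(read.csv(file.path(out, "truth_puncta.csv")))))
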