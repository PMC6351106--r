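#!/usr/bin/env Rscript
# Tandem mCherry-GFP-LC3 flux readout: detect puncta on the red channel,
# classify each as autophagosome (green+red) or autolysosome (red only),
# and compare the recovered autolysosome fraction with the generator truth.

suppressPackageStartupMessages(library(punctaflux))

manifest <- read.csv("results/dataset/manifest.csv")
manifest <- manifest[manifest$condition == "tandem", ]
truth <- read.csv("results/dataset/truth_puncta.csv")
truth <- truth[truth$name %in% manifest$name, ]

imgs <- lapply(seq_len(nrow(manifest)), function(i)
  list(blue = manifest$blue[i], green = manifest$green[i],
       red = manifest$red[i], name = manifest$name[i],
       condition = "tandem"))

rep <- run_pipeline(validate_config(list(
  mode = "tandem", seed = 20260930, out_dir = "results/tandem",
  images = imgs)))

n_ap <- sum(rep$summaries$n_autophagosome)
n_al <- sum(rep$summaries$n_autolysosome)
message(sprintf("classified %d autophagosomes + %d autolysosomes", n_ap, n_al))
message(sprintf("autolysosome fraction: recovered %.3f vs generated %.3f",
                n_al / (n_ap + n_al),
                mean(truth$class == "autolysosome")))
message("labeled puncta in results/tandem/puncta.csv")
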