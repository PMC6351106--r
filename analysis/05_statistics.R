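#!/usr/bin/env Rscript
# Condition-level statistics on the puncta quantification: mean +/- SD per
# condition and the unpaired Student's t-test on per-image puncta area per
# cell, reported the way the bar-chart comparisons are.

suppressPackageStartupMessages(library(punctaflux))

summ <- read.csv("results/puncta/summary.csv")
a <- summ$puncta_area_per_cell[summ$condition == "control"]
b <- summ$puncta_area_per_cell[summ$condition == "induced"]

for (nm in c("control", "induced")) {
  v <- summ$puncta_area_per_cell[summ$condition == nm]
  ms <- mean_sd(v)
  message(sprintf("%s: %.1f +/- %.1f px^2 per cell (n = %d images)",
                  nm, ms["mean"], ms["sd"], length(v)))
}

tt <- unpaired_t_test(a, b)
print(tt)
out <- data.frame(group_a = "control", group_b = "induced",
                  mean_a = tt$mean_a, sd_a = tt$sd_a, n_a = tt$n_a,
                  mean_b = tt$mean_b, sd_b = tt$sd_b, n_b = tt$n_b,
                  t = tt$t, df = tt$df, p_value = tt$p_value,
                  significant = tt$significant)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/statistics.csv", row.names = FALSE)
message("comparison table in results/statistics.csv")
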