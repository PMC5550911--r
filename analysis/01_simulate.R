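#!/usr/bin/env Rscript
# Stage 1: simulate the acclimation study -- 1532 proteins quantified in two
# conditions (18C control, 22C elevated) with five biological replicates
# each, 31 truly up- and 31 truly down-regulated proteins with log10 fold
# changes spanning 0.2..2.2, multiplicative log-normal noise (CV 25%), 5%
# missingness and a constant spiked peptide. Writes the raw intensity
# matrix, the condition map and the ground truth under results/simulated/.

library(lfqde)

outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = 1)
sim <- generate_intensity_matrix(cfg)

write_quant_matrix(sim$matrix, file.path(outdir, "intensity_matrix.tsv"))
write.table(sim$truth, file.path(outdir, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_missing <- sum(is.na(sim$matrix$values))
cat(sprintf(
  "Simulated %d proteins x %d samples (seed %d): %d up, %d down, %.1f%% cells missing.\n",
  cfg$n_proteins, ncol(sim$matrix$values), cfg$seed,
  sum(sim$truth$class == "up"), sum(sim$truth$class == "down"),
  100 * n_missing / length(sim$matrix$values)))
cat("Spike row complete:", !anyNA(sim$matrix$values[cfg$spike_label, ]), "\n")
cat("Outputs in", outdir, "\n")
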