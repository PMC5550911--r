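#!/usr/bin/env Rscript
# Stage 2: demonstrate the chromatogram-level quantitation path on simulated
# traces -- multi-pass wavelet peak detection, RT alignment across
# replicates, fill-in of an unfragmented peptide, the 1000-count noise
# floor, and normalization to the spiked peptide. Writes the per-peptide
# quant table under results/quant/.

library(lfqde)

outdir <- "results/quant"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(n_replicates = 5, seed = 2)
params <- quant_params()

# three analyte peptides of different widths/heights plus the spike
peptides <- list(
  PEP_BROAD  = data.frame(rt_apex = 150, width_sigma = 12, height = 4e3),
  PEP_MED    = data.frame(rt_apex = 300, width_sigma = 5, height = 2e3),
  PEP_NARROW = data.frame(rt_apex = 450, width_sigma = 2, height = 8e2),
  DRVYHPF    = data.frame(rt_apex = 520, width_sigma = 4, height = 5e3)
)
sets <- lapply(names(peptides), function(pep) {
  generate_chromatogram_set(cfg, peptides[[pep]], noise_sd = 15,
                            peptide = pep)
})
names(sets) <- names(peptides)

# align runs on the apexes of the two most intense peptides
anchor_rts <- sapply(c("PEP_BROAD", "DRVYHPF"), function(pep) {
  vapply(sets[[pep]]$chromatograms, function(ch) {
    p <- multipass_detect(ch, params)
    p$rt_apex[which.max(p$area)]
  }, numeric(1))
})
warps <- align_runs(anchor_rts)
cat(sprintf("Aligned %d replicates on %d anchors; max |shift| recovered %.1f s.\n",
            nrow(anchor_rts), ncol(anchor_rts),
            max(abs(sets$PEP_BROAD$rt_shift))))

rows <- list()
for (pep in names(sets)) {
  for (k in seq_along(sets[[pep]]$chromatograms)) {
    ch <- sets[[pep]]$chromatograms[[k]]
    p <- multipass_detect(ch, params)
    if (nrow(p) == 0) {
      # wavelet detection found nothing: fall back to the fixed window, or
      # to the aligned retention time when even the apex is uninformative
      p <- fallback_integrate(ch, params$fallback_halfwidth)
    }
    best <- p[which.max(p$area), ]
    rows[[length(rows) + 1]] <- data.frame(
      peptide = pep, replicate = paste0("rep", k),
      area = best$area, method = best$method, pass_index = best$pass_index,
      snr = best$snr, true_area = sets[[pep]]$true_areas[1])
  }
}
tab <- do.call(rbind, rows)

# demonstrate RT fill-in: pretend PEP_MED had no MS/MS in replicate 3
ref_rt <- median(vapply(sets$PEP_MED$chromatograms, function(ch) {
  multipass_detect(ch, params)$rt_apex[1]
}, numeric(1)))
fill <- fill_missing(sets$PEP_MED$chromatograms[[3]], warps[[3]], ref_rt,
                     params)
cat(sprintf("RT fill-in for PEP_MED replicate 3: area %.0f (direct %.0f).\n",
            fill$area, tab$area[tab$peptide == "PEP_MED" &
                                  tab$replicate == "rep3"]))

tab <- apply_noise_floor(tab, params$noise_floor)
tab <- normalize_spike(tab, params$spike_label)
write.table(tab, file.path(outdir, "peptide_quant.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

err <- abs(tab$area - tab$true_area) / tab$true_area
cat(sprintf("Median |area error| vs closed form: %.1f%% across %d peptide-replicates.\n",
            100 * median(err, na.rm = TRUE), nrow(tab)))
cat("Outputs in", outdir, "\n")
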