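#!/usr/bin/env Rscript
# Stage 4: ordination of the differential proteins -- correlation-matrix PCA
# of the sample profiles (variance explained from unrotated eigenvalues,
# promax-rotated loadings reported alongside) and Pearson/average-linkage
# clustering for heat-map row and column order. Writes results/ordination/.

library(lfqde)

outdir <- "results/ordination"
if (!file.exists("results/de/de_table.tsv"))
  stop("run analysis/03_differential_expression.R first")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

qm <- read_quant_matrix("results/simulated/intensity_matrix.tsv")
de <- read.delim("results/de/de_table.tsv")
qm <- subset_quant_matrix(qm, proteins = setdiff(rownames(qm$values),
                                                 "DRVYHPF"))
lg <- log10_transform(filter_missingness(qm))
de_proteins <- de$protein[de$call != "ns"]
cat(sprintf("Ordination on the %d differential proteins.\n",
            length(de_proteins)))

pca <- run_pca(lg, proteins = de_proteins)
pca_rot <- run_pca(lg, proteins = de_proteins, rotation = "promax")
cat(sprintf("PC1 explains %.1f%% of the variation, PC2 an additional %.1f%%.\n",
            pca$variance_pct[1], pca$variance_pct[2]))

pc1 <- pca$scores[, 1]
ctrl <- pc1[pca$condition == "control_18C"]
elev <- pc1[pca$condition == "elevated_22C"]
cat(sprintf("PC1 separation between conditions: margin %.2f.\n",
            max(min(elev) - max(ctrl), min(ctrl) - max(elev))))

cl <- pearson_cluster(lg, proteins = de_proteins)
cat("Sample dendrogram order:", paste(cl$col_order, collapse = " "), "\n")

write.table(data.frame(component = seq_along(pca$variance_pct),
                       variance_pct = pca$variance_pct),
            file.path(outdir, "pca_variance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = rownames(pca$scores),
                       condition = pca$condition,
                       pca$scores[, 1:3]),
            file.path(outdir, "pca_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(protein = rownames(cl$ordered_values),
                       cl$ordered_values, check.names = FALSE),
            file.path(outdir, "heatmap_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Outputs in", outdir, "\n")
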