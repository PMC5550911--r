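#!/usr/bin/env Rscript
# Stage 5: overrepresentation of annotation categories in the differential
# set against the full quantified reference list, by exact two-sided
# hypergeometric test with BH correction. Uses the simulated annotation map
# (13% of proteins unannotated, one stress-like category loaded with
# regulated proteins, one biosynthetic-like category mostly null). Writes
# results/enrichment/.

library(lfqde)

outdir <- "results/enrichment"
if (!file.exists("results/de/de_table.tsv"))
  stop("run analysis/03_differential_expression.R first")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

de <- read.delim("results/de/de_table.tsv")
truth <- read.delim("results/simulated/ground_truth.tsv")
de_proteins <- de$protein[de$call != "ns"]

ann <- generate_annotation_map(de$protein, truth, seed = 1)
enr <- overrepresentation(de_proteins, de$protein, ann)

cat(sprintf("%d categories tested; %d significant after BH at 0.05.\n",
            nrow(enr), sum(enr$significant)))
top <- utils::head(enr, 5)
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-22s %2d/%3d observed, expected %5.2f, %5.2fx %s, q = %.3g\n",
              top$category[i], top$n_de_in_cat[i], top$n_ref_in_cat[i],
              top$expected[i], top$fold_enrichment[i], top$direction[i],
              top$q[i]))
}
under <- enr[enr$direction == "under" & enr$significant, ]
cat(sprintf("Under-represented significant categories: %s.\n",
            if (nrow(under)) paste(under$category, collapse = ", ") else "none"))

write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Outputs in", outdir, "\n")
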