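# lfqde

Label-free shotgun-proteomics quantitation and differential-expression
analysis for two-condition replicate designs, built for studies that
compare protein abundance between physiological states — the motivating
case is an invertebrate ovary acclimated to a control (18°C) versus an
elevated (22°C) seawater temperature, five biological replicates per
condition.

The package covers the full path from chromatogram to biology:

* **Quantitation** — selected ion chromatogram (SIC) extraction in a 10 ppm
  m/z window; multi-pass continuous-wavelet (Ricker) peak detection over
  narrowing width ranges (minimum widths 20→2 s, maximum 80 s, S/N ≥ 10,
  peak limits by descent on the raw trace); fallback fixed-window
  integration; retention-time alignment by monotone piecewise-linear warps
  and RT fill-in for unfragmented peptides; a 1000-count noise floor
  (sub-floor areas become *missing*, never zero); normalization to the
  spiked peptide DRVYHPF.
* **Assembly** — peptide→protein roll-up, elimination of proteins missing
  more than one measurement per condition, log10 transform.
* **Differential expression** — per protein, two-sided Student's *t* and
  exact Mann–Whitney *U* on the log10 values, Benjamini–Hochberg Q-values,
  and an anchor-derived fold-change cutoff: the smallest-fold-change
  protein with Q < 0.05 sets the cutoff at |10·log10 FC| truncated to one
  decimal (a 1.6-fold anchor ⇒ 2.0 dB ⇒ linear thresholds 1.58 up / 0.63
  down). A protein is called up/down only when **both** p-values are < 0.05
  **and** its fold change is beyond the threshold.
* **Ordination** — correlation-matrix PCA of sample profiles (variance
  fractions from unrotated eigenvalues; optional promax-rotated loadings)
  and Pearson/average-linkage clustering for heat-map ordering.
* **Enrichment** — exact two-sided hypergeometric over/under-representation
  of flat annotation categories in the DE set against the quantified
  reference list, BH-corrected.
* **Synthetic data** — a generator emulating the 2×5 design (1532 proteins,
  31 up + 31 down with log10 effects spanning 0.2–2.2, log-normal noise,
  MCAR missingness, constant spike row) with ground truth for
  parameter-recovery testing.

## Worked example

The numbered scripts under `analysis/` run the study end to end on
synthetic data (`Rscript analysis/01_simulate.R`, then 02–05). The
equivalent in code:

```r
library(lfqde)

sim <- generate_intensity_matrix(synth_config(seed = 1))
qm  <- subset_quant_matrix(sim$matrix,
          proteins = setdiff(rownames(sim$matrix$values), "DRVYHPF"))
lg  <- log10_transform(filter_missingness(qm))
de  <- call_de(lg, de_config())        # anchor-derived cutoff
pca <- run_pca(lg, proteins = de$protein[de$call != "ns"])
```

Running `analysis/01_simulate.R` and `analysis/03_differential_expression.R`
prints:

```
Simulated 1532 proteins x 10 samples (seed 1): 31 up, 31 down, 5.1% cells missing.
Missingness filter: 1466 of 1532 proteins retained (66 removed).
Anchor P0120 -> cutoff 1.5 dB, linear thresholds 1.41 / 0.71.
Calls: 34 up, 36 down, 1396 ns.
Against ground truth: sensitivity 1.00, false-discovery proportion 0.21.
```

Reading: 66 proteins were eliminated for missing more than one measurement
in a condition; among proteins with Q < 0.05 the smallest observed fold
change (protein P0120) set the cutoff at 1.5 dB, i.e. calls require a
fold change above 1.41 or below 0.71 *and* both tests significant; all 62
truly regulated proteins were recovered, at the cost of some false calls
admitted by this liberal simulated anchor. `analysis/04_ordination.R` then
reports

```
PC1 explains 85.7% of the variation, PC2 an additional 3.4%.
PC1 separation between conditions: margin 14.41.
```

— the elevated-temperature samples separate from the controls on the first
component, and `analysis/05_enrichment.R` finds the simulated
stress-response-like category 20.9× over-represented (q ≈ 3e-42) in the DE
set.

To analyse an external intensity table instead, map its columns and ingest:

```r
path <- system.file("extdata", "synthetic_intensity_table.tsv", package = "lfqde")
qm <- ingest_matrix(path, list(protein = "protein",
                               control  = paste0("R18_", LETTERS[1:5]),
                               elevated = paste0("R22_", LETTERS[1:5])))
```

(`inst/extdata/synthetic_intensity_table.tsv` is a small synthetic example
of the layout; `reproduce_supplementary()` wraps the full
filter→log10→tests→thresholds→PCA reproduction for such a table and
reports both fold-change bases and both BH input families.)

## Documentation

The methods vignette
(`vignettes/label-free-quantitation-workflow.Rmd`) documents the model and
its assumptions, every tunable parameter with units and defaults, the
numerical choices (noise estimator, descent baseline, truncation,
tie handling), what the synthetic generator does and does not emulate, and
known limitations.
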