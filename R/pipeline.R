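#' Pipeline configuration
#'
#' Bundles the stage configurations; every default equals the
#' acquisition-matched parameter where one exists (10 ppm mass window, peak
#' widths 2-20 s minimum / 80 s maximum, S/N 10, noise floor 1000, alpha
#' 0.05, fallback cutoff 2.0 dB, 5 replicates per condition).
#'
#' @param synth A [synth_config()] (study emulation; ignored when a matrix
#'   is supplied to [run_pipeline()]).
#' @param quant A [quant_params()].
#' @param de A [de_config()].
#' @param annotation Optional annotation map (named list protein -> terms);
#'   `NULL` simulates one from the ground truth.
#' @param pca_scope `"de_only"` (ordination on the differential proteins,
#'   default) or `"all"`.
#' @param enrich_alpha Significance level for the enrichment stage.
#' @param seed Overrides `synth$seed` when not `NULL`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            quant = quant_params(),
                            de = de_config(),
                            annotation = NULL,
                            pca_scope = c("de_only", "all"),
                            enrich_alpha = 0.05,
                            seed = NULL) {
  if (!is.null(seed)) synth$seed <- as.integer(seed)
  structure(list(synth = synth, quant = quant, de = de,
                 annotation = annotation,
                 pca_scope = match.arg(pca_scope),
                 enrich_alpha = enrich_alpha),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized top-level blocks: `synth`, `quant`, `de`, `pca_scope`,
#' `enrich_alpha`, `seed`; each block holds arguments for the matching
#' constructor.
#'
#' @param path `.yml`/`.yaml` (needs the yaml package) or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  pipeline_config(
    synth = do.call(synth_config, as.list(raw$synth %||% list())),
    quant = do.call(quant_params, as.list(raw$quant %||% list())),
    de = do.call(de_config, as.list(raw$de %||% list())),
    pca_scope = raw$pca_scope %||% "de_only",
    enrich_alpha = raw$enrich_alpha %||% 0.05,
    seed = raw$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(logfile, stage, fmt, ...) {
  msg <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(msg)
}

#' Run the full analysis pipeline
#'
#' Executes simulation (or ingestion) -> assembly (missingness filter,
#' log10) -> differential-expression calling -> ordination (PCA and Pearson
#' clustering of the differential proteins) -> overrepresentation, writing
#' every stage output plus a machine-readable summary JSON and a log file
#' under `outdir`. Any stage error aborts with the stage name. When no
#' protein reaches the anchor Q-value criterion the fold-change cutoff falls
#' back to `de$cutoff_fallback_db` (logged).
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created if needed); `NULL` skips all file
#'   output.
#' @param matrix Optional pre-made raw-scale [quant_matrix()] (e.g. from
#'   [ingest_matrix()]); skips the simulation stage.
#' @return Invisibly, the summary list (`n_proteins_in`, `n_retained`,
#'   `n_up`, `n_down`, `n_ns`, `cutoff_db`, `cutoff_source`, `anchor`,
#'   `thresholds`, `variance_pct` (first two PCs), `n_enriched`, `seed`),
#'   plus the stage objects in attribute `stages`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = NULL,
                         matrix = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  logfile <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(outdir, "pipeline.log")
    cat(sprintf("lfqde %s | R %s | seed %d\n",
                as.character(utils::packageVersion("lfqde")),
                paste(R.version$major, R.version$minor, sep = "."),
                cfg$synth$seed),
        file = logfile)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  spike <- cfg$synth$spike_label
  if (is.null(matrix)) {
    sim <- run_stage("synth", generate_intensity_matrix(cfg$synth))
    qm_raw <- sim$matrix
    truth <- sim$truth
    stage_log(logfile, "synth", "%d proteins x %d samples simulated (seed %d)",
              nrow(qm_raw$values) - 1L, ncol(qm_raw$values), cfg$synth$seed)
  } else {
    qm_raw <- matrix
    stopifnot(inherits(qm_raw, "quant_matrix"))
    stage_log(logfile, "ingest", "%d proteins x %d samples supplied",
              nrow(qm_raw$values), ncol(qm_raw$values))
  }

  qm_stat <- if (spike %in% rownames(qm_raw$values)) {
    subset_quant_matrix(qm_raw,
                        proteins = setdiff(rownames(qm_raw$values), spike))
  } else qm_raw

  filtered <- run_stage("assemble", filter_missingness(qm_stat))
  stage_log(logfile, "assemble", "%d of %d proteins retained by the missingness filter",
            nrow(filtered$values), nrow(qm_stat$values))
  lg <- run_stage("assemble", log10_transform(filtered))

  cutoff_source <- if (is.null(cfg$de$cutoff_db)) "anchor_derived" else "fixed"
  de <- tryCatch(
    run_stage("destats", call_de(lg, cfg$de)),
    error = function(e) {
      if (grepl("cannot derive a cutoff", conditionMessage(e))) {
        cfg2 <- cfg$de
        cfg2$cutoff_db <- cfg$de$cutoff_fallback_db
        stage_log(logfile, "destats",
                  "no anchor candidate (q < %.2f); falling back to fixed cutoff %.1f dB",
                  cfg$de$anchor_q_max, cfg2$cutoff_db)
        cutoff_source <<- "fixed_fallback"
        call_de(lg, cfg2)
      } else stop(e)
    }
  )
  n_up <- sum(de$call == "up")
  n_down <- sum(de$call == "down")
  stage_log(logfile, "destats",
            "%d up, %d down, %d ns at cutoff %.1f dB (%s)",
            n_up, n_down, sum(de$call == "ns"),
            attr(de, "cutoff_db"), cutoff_source)

  de_proteins <- de$protein[de$call != "ns"]
  ord_proteins <- if (cfg$pca_scope == "de_only" && length(de_proteins) >= 3L)
    de_proteins else NULL
  pca <- run_stage("ordination", run_pca(lg, proteins = ord_proteins))
  clus <- if (length(de_proteins) >= 2L)
    run_stage("ordination", pearson_cluster(lg, proteins = de_proteins))
  else NULL
  stage_log(logfile, "ordination",
            "PCA on %s proteins: PC1 %.1f%%, PC2 %.1f%%",
            if (is.null(ord_proteins)) "all" else
              as.character(length(ord_proteins)),
            pca$variance_pct[1], pca$variance_pct[2])

  enr <- NULL
  if (length(de_proteins) >= 1L) {
    ann <- cfg$annotation
    if (is.null(ann) && !is.null(truth))
      ann <- generate_annotation_map(de$protein, truth,
                                     seed = cfg$synth$seed)
    if (!is.null(ann)) {
      enr <- run_stage("enrich",
                       overrepresentation(de_proteins, de$protein, ann,
                                          alpha = cfg$enrich_alpha))
      stage_log(logfile, "enrich",
                "%d of %d categories significant at BH %.2f",
                sum(enr$significant), nrow(enr), cfg$enrich_alpha)
    }
  } else {
    stage_log(logfile, "enrich", "skipped: no differential proteins")
  }

  summary <- list(
    n_proteins_in = nrow(qm_stat$values),
    n_retained = nrow(filtered$values),
    n_up = n_up, n_down = n_down, n_ns = sum(de$call == "ns"),
    cutoff_db = attr(de, "cutoff_db"),
    cutoff_source = cutoff_source,
    anchor = attr(de, "anchor"),
    thresholds = as.list(attr(de, "thresholds")),
    variance_pct = as.numeric(pca$variance_pct[1:2]),
    n_enriched = if (is.null(enr)) 0L else sum(enr$significant),
    seed = cfg$synth$seed
  )

  if (!is.null(outdir)) {
    write_quant_matrix(qm_raw, file.path(outdir, "intensity_matrix.tsv"))
    utils::write.table(de, file.path(outdir, "de_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(component = seq_along(pca$variance_pct),
                 variance_pct = pca$variance_pct),
      file.path(outdir, "pca_variance.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(sample = rownames(pca$scores), condition = pca$condition,
                 pca$scores[, 1:min(3, ncol(pca$scores)), drop = FALSE]),
      file.path(outdir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(clus)) {
      utils::write.table(
        data.frame(protein = rownames(clus$ordered_values),
                   clus$ordered_values, check.names = FALSE),
        file.path(outdir, "heatmap_matrix.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    if (!is.null(enr))
      utils::write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(truth))
      utils::write.table(truth, file.path(outdir, "ground_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(summary, "stages") <- list(matrix = qm_raw, truth = truth,
                                  filtered = filtered, log10 = lg, de = de,
                                  pca = pca, cluster = clus, enrichment = enr)
  invisible(summary)
}

#' Ingest an external protein intensity table
#'
#' Reads a TSV of protein intensities (e.g. a supplementary data table) into
#' a [quant_matrix()] using a column map naming the protein-ID column and
#' the sample columns per condition. Malformed numeric cells become missing,
#' with a warning giving the count.
#'
#' @param path TSV path.
#' @param column_map List with entries `protein` (column name), `control`
#'   and `elevated` (character vectors of sample column names).
#' @return A raw-scale [quant_matrix()] with attribute `n_malformed`.
#' @export
ingest_matrix <- function(path, column_map) {
  stopifnot(all(c("protein", "control", "elevated") %in% names(column_map)))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  wanted <- c(column_map$protein, column_map$control, column_map$elevated)
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols) > 0L)
    stop("required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  samples <- c(column_map$control, column_map$elevated)
  v <- sapply(samples, function(cn) {
    suppressWarnings(as.numeric(df[[cn]]))
  })
  v <- matrix(v, nrow = nrow(df),
              dimnames = list(make.unique(as.character(df[[column_map$protein]])),
                              samples))
  n_malformed <- sum(is.na(v) &
                       !is.na(as.matrix(df[samples])) &
                       as.matrix(df[samples]) != "")
  if (n_malformed > 0L)
    warning(n_malformed, " non-numeric cell(s) set to missing")
  qm <- quant_matrix(v, c(rep("control_18C", length(column_map$control)),
                          rep("elevated_22C", length(column_map$elevated))),
                     log10 = FALSE)
  attr(qm, "n_malformed") <- n_malformed
  qm
}

#' Reproduce the published analysis from a supplementary intensity table
#'
#' Convenience wrapper: ingest the externally obtained intensity table, then
#' run missingness filter -> log10 -> dual tests -> BH -> anchor-derived
#' thresholds -> PCA on the differential proteins, reporting both
#' fold-change bases and both BH input families (the two analysis choices
#' the original report leaves open).
#'
#' @param path TSV path of the intensity table.
#' @param column_map See [ingest_matrix()].
#' @return List with `de` (anchor-derived, t-based BH, arithmetic means),
#'   `de_variants` (the three alternative configurations), `pca`
#'   (unrotated) and `pca_promax`, plus `summary` counts.
#' @export
reproduce_supplementary <- function(path, column_map) {
  qm <- ingest_matrix(path, column_map)
  lg <- log10_transform(filter_missingness(qm))
  variants <- list(
    arithmetic_t = de_config(),
    geometric_t = de_config(fold_change_basis = "geometric_means"),
    arithmetic_u = de_config(bh_on = "p_u"),
    geometric_u = de_config(fold_change_basis = "geometric_means",
                            bh_on = "p_u")
  )
  de_all <- lapply(variants, function(cfg) call_de(lg, cfg))
  de <- de_all$arithmetic_t
  de_proteins <- de$protein[de$call != "ns"]
  pca <- run_pca(lg, proteins = de_proteins)
  pca_promax <- run_pca(lg, proteins = de_proteins, rotation = "promax")
  list(
    de = de,
    de_variants = de_all[-1],
    pca = pca,
    pca_promax = pca_promax,
    summary = list(
      n_retained = nrow(lg$values),
      n_up = sum(de$call == "up"),
      n_down = sum(de$call == "down"),
      cutoff_db = attr(de, "cutoff_db"),
      anchor = attr(de, "anchor"),
      variance_pct = as.numeric(pca$variance_pct[1:2])
    )
  )
}
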