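## Project runner: wires the stages (parse -> harmonize -> consensus ->
## annotate -> express -> report) into a run directory, driven by a YAML
## config plus a sample metadata table. Stage outputs are written to
## subdirectories as they complete, so a failing stage leaves the earlier
## outputs in place. The pipeline is deterministic: rerunning on unchanged
## inputs reproduces the outputs byte for byte.

OUT_OF_SCOPE_KEYS <- c("BWA_PARAMS", "HISAT2_PARAMS", "STAR_PARAMS",
                       "BOWTIE2_PARAMS", "SEGEMEHL_PARAMS", "PREPROCESSOR",
                       "PREPROCESSOR_PARAMS", "GENOME_FASTA",
                       "CUFFNORM_EXTRA_PARAMS", "TOGGLE_TRANSCRIPTOME_RECONSTRUCTION")

#' Read and validate a run configuration
#'
#' The YAML config names the sample metadata table, the GTF annotation, the
#' output directory and the consensus/expression options. The metadata TSV
#' must have columns `sample_id`, one path column per enabled method, and
#' `total_mapped_reads`; optional `expression` (per-sample gene expression
#' table) and `group`. Relative paths are resolved against the metadata
#' file's directory. Read-alignment parameters of the upstream detectors are
#' not this tool's business and are rejected if present.
#'
#' @param path YAML config file.
#' @return a validated `run_config` list with the loaded metadata table.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  bad <- intersect(names(cfg), OUT_OF_SCOPE_KEYS)
  if (length(bad))
    stop("config error: parameter(s) ", paste(bad, collapse = ", "),
         " concern read alignment/preprocessing, which is outside this tool; ",
         "remove them from the config", call. = FALSE)
  for (f in c("metadata", "annotation", "output_dir"))
    if (is.null(cfg[[f]]))
      stop("config error: missing required field '", f, "'", call. = FALSE)
  defaults <- list(methods = CIRC_METHODS, min_methods = 2L, min_reads = 2L,
                   scope = "pooled", support_statistic = "max",
                   count_rule = "max", pseudocount = 1, min_cor_samples = 3L,
                   html = TRUE)
  for (f in names(defaults)) if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  cfg$methods <- unlist(cfg$methods)
  base <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  cfg$annotation <- resolve(cfg$annotation)
  cfg$metadata <- resolve(cfg$metadata)
  if (!file.exists(cfg$annotation))
    stop("config error: annotation file not found: ", cfg$annotation, call. = FALSE)
  if (!file.exists(cfg$metadata))
    stop("config error: metadata file not found: ", cfg$metadata, call. = FALSE)

  meta <- fread(cfg$metadata, sep = "\t", header = TRUE)
  need <- c("sample_id", cfg$methods, "total_mapped_reads")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("config error: metadata table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("config error: duplicate sample_id in metadata", call. = FALSE)
  mbase <- dirname(normalizePath(cfg$metadata, mustWork = TRUE))
  for (col in c(cfg$methods, intersect("expression", names(meta)))) {
    p <- meta[[col]]
    p <- ifelse(grepl("^/", p), p, file.path(mbase, p))
    set(meta, j = col, value = p)
    gone <- p[!file.exists(p)]
    if (length(gone))
      stop("config error: file referenced by metadata column '", col,
           "' not found: ", gone[1], call. = FALSE)
  }
  cfg$meta <- meta
  ## validates thresholds against the enabled methods
  cfg$consensus <- consensus_config(cfg$min_methods, cfg$min_reads,
                                    cfg$methods, cfg$scope,
                                    cfg$support_statistic)
  structure(cfg, class = "run_config")
}

#' Execute the full consensus pipeline for a validated configuration
#'
#' Runs parse, harmonize, consensus, annotation, expression and report
#' stages, writing each stage's tables under `output_dir`
#' (`circrnas/`, `annotation/`, `expression/`, `report/`).
#'
#' @param cfg a `run_config` from [read_run_config()].
#' @return invisibly, a list with the in-memory stage outputs: `evidence`,
#'   `reliable`, `junctions`, `annotations`, `circ_rpm`, `correlations`,
#'   `stats`.
#' @export
run_project <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  ## stage 1-2: parse + harmonize
  calls <- rbindlist(lapply(seq_len(nrow(cfg$meta)), function(i) {
    rbindlist(lapply(cfg$methods, function(m)
      parse_detector_output(cfg$meta[[m]][i], m, cfg$meta$sample_id[i])))
  }))
  ev <- harmonize_calls(calls)
  dir.create(file.path(out, "circrnas"), showWarnings = FALSE)
  write_circrna_table(circ_junctions(ev),
                      file.path(out, "circrnas", "circrnas_union.tsv"))

  ## stage 3: consensus
  reliable <- select_reliable(ev, cfg$consensus)
  rel_j <- circ_junctions(reliable)
  write_circrna_table(rel_j, file.path(out, "circrnas", "circrnas_reliable.tsv"))

  ## stage 4: annotation
  genes <- parse_gtf(cfg$annotation)
  idx <- build_exon_index(genes)
  ann <- categorize_circrna(rel_j, idx)
  dir.create(file.path(out, "annotation"), showWarnings = FALSE)
  fwrite(ann, file.path(out, "annotation", "circrna_annotation.tsv"), sep = "\t")
  if (nrow(ann)) {
    bed <- rel_j[ann, on = "circ_id"]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", bed$chrom, bed$start, bed$end,
                       bed$category, pmin(bed$total_reads, 1000L), bed$strand),
               file.path(out, "annotation", "circrna_annotation.bed"))
  } else writeLines(character(), file.path(out, "annotation", "circrna_annotation.bed"))

  ## stage 5: expression
  totals <- setNames(as.numeric(cfg$meta$total_mapped_reads), cfg$meta$sample_id)
  circ_rpm <- circrna_matrix(reliable, totals, count_rule = cfg$count_rule)
  dir.create(file.path(out, "expression"), showWarnings = FALSE)
  fwrite(data.table(circ_id = rownames(circ_rpm), as.data.table(circ_rpm)),
         file.path(out, "expression", "circrna_rpm.tsv"), sep = "\t")
  correlations <- NULL
  if ("expression" %in% names(cfg$meta)) {
    exprs <- lapply(seq_len(nrow(cfg$meta)), function(i)
      parse_expression_table(cfg$meta$expression[i],
                             cfg$meta$total_mapped_reads[i],
                             cfg$meta$sample_id[i]))
    gm <- gene_matrix(exprs)
    correlations <- correlate(circ_rpm, gm, ann,
                              min_samples = cfg$min_cor_samples)
    fwrite(correlations,
           file.path(out, "expression", "circrna_gene_correlation.tsv"),
           sep = "\t")
  }

  ## stage 6: report
  stats <- build_summary(ev, reliable, ann, correlations, cfg$methods)
  render_summary(stats, file.path(out, "report"), html = isTRUE(cfg$html))

  invisible(list(evidence = ev, reliable = reliable, junctions = rel_j,
                 annotations = ann, circ_rpm = circ_rpm,
                 correlations = correlations, stats = stats))
}
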