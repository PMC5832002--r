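## circRNA expression: RPM normalization, expression matrices, replicate-free
## log2 fold changes, cumulative-expression summaries and circRNA/host-gene
## Spearman correlation.

#' Reads per million mapped reads
#'
#' @param read_count back-splice read count(s).
#' @param total_mapped_reads total mapped reads of the sample (> 0).
#' @return `read_count * 1e6 / total_mapped_reads`.
#' @export
rpm <- function(read_count, total_mapped_reads) {
  if (any(total_mapped_reads <= 0))
    stop("total_mapped_reads must be > 0", call. = FALSE)
  read_count * 1e6 / total_mapped_reads
}

#' circRNA x sample expression matrix in RPM
#'
#' Per-sample read counts of a junction are first reduced across methods by
#' `count_rule` (default: the maximum over methods, consistent with the
#' consensus support statistic), then divided by the sample's total mapped
#' reads. Junctions without evidence in a sample get 0.
#'
#' @param ev `circ_evidence` table (typically the reliable subset).
#' @param totals named numeric vector, sample_id -> total mapped reads; must
#'   cover every sample present in `ev`.
#' @param count_rule `"max"`, `"sum"` or `"mean"` over methods.
#' @param unit `"RPM"` (default) or `"raw"` (no normalization).
#' @return numeric matrix, rows = circRNA display IDs (genomic order),
#'   columns = sample ids (order of `totals`), attribute `unit`.
#' @export
circrna_matrix <- function(ev, totals, count_rule = c("max", "sum", "mean"),
                           unit = c("RPM", "raw")) {
  count_rule <- match.arg(count_rule)
  unit <- match.arg(unit)
  ev <- as.data.table(ev)
  miss <- setdiff(unique(ev$sample_id), names(totals))
  if (length(miss))
    stop("no total_mapped_reads for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples <- names(totals)
  jn <- circ_junctions(ev)
  m <- matrix(0, nrow = nrow(jn), ncol = length(samples),
              dimnames = list(jn$circ_id, samples))
  if (nrow(ev)) {
    red <- switch(count_rule,
      max = ev[, .(value = as.numeric(max(read_count))),
               by = .(chrom, start, end, strand, sample_id)],
      sum = ev[, .(value = as.numeric(sum(read_count))),
               by = .(chrom, start, end, strand, sample_id)],
      mean = ev[, .(value = mean(read_count)),
                by = .(chrom, start, end, strand, sample_id)]
    )
    red[, circ_id := circrna_id(chrom, start, end, strand)]
    m[cbind(red$circ_id, red$sample_id)] <- red$value
  }
  if (unit == "RPM") m <- sweep(m, 2L, unname(totals), function(x, t) x * 1e6 / t)
  attr(m, "unit") <- unit
  m
}

#' Gene x sample FPKM matrix from per-sample expression tables
#'
#' @param expressions list of `sample_expression` objects
#'   ([parse_expression_table()]).
#' @return numeric matrix of FPKM, rows = gene ids (union, sorted), columns =
#'   sample ids; genes absent from a sample get 0.
#' @export
gene_matrix <- function(expressions) {
  ids <- vapply(expressions, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  genes <- sort(unique(unlist(lapply(expressions, function(e) e$expr$gene_id))))
  m <- matrix(0, nrow = length(genes), ncol = length(ids),
              dimnames = list(genes, ids))
  for (e in expressions) m[e$expr$gene_id, e$sample_id] <- e$expr$FPKM
  attr(m, "unit") <- "FPKM"
  m
}

#' Replicate-free log2 fold change with pseudocount
#'
#' `log2((a + pseudocount) / (b + pseudocount))`. With no replicates and
#' frequent zeros, the pseudocount (default 1 RPM) keeps the ratio defined
#' and shrinks fold changes of barely-expressed circRNAs.
#'
#' @param a,b non-negative expression values (e.g. RPM), vectorized.
#' @param pseudocount added to both; must be > 0 if any input is 0.
#' @return log2 fold change(s) of `a` versus `b`.
#' @export
log2fc <- function(a, b, pseudocount = 1) {
  if (any(a < 0) || any(b < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (pseudocount <= 0 && any(a == 0 | b == 0))
    stop("pseudocount must be > 0 when values can be 0", call. = FALSE)
  log2((a + pseudocount) / (b + pseudocount))
}

#' Count up/down-regulated values at a fold-change threshold
#'
#' @param fc vector of log2 fold changes.
#' @param threshold positive threshold (default 1.5, i.e. |log2FC| > 1.5).
#' @return named integer vector `c(n_up, n_down)`: counts of `fc > threshold`
#'   and `fc < -threshold`.
#' @export
fc_threshold_counts <- function(fc, threshold = 1.5) {
  stopifnot(threshold > 0)
  c(n_up = sum(fc > threshold), n_down = sum(fc < -threshold))
}

#' Rows needed to account for a fraction of a sample's expression
#'
#' The minimal number of rows, taken in descending value order, whose sum
#' reaches at least `fraction` of the column total.
#'
#' @param m expression matrix.
#' @param sample column (sample id or index).
#' @param fraction target fraction of total expression, in (0, 1].
#' @return integer count of rows.
#' @export
cumulative_share <- function(m, sample, fraction = 0.75) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- m[, sample]
  tot <- sum(v)
  if (tot <= 0) stop("column has no expression", call. = FALSE)
  cs <- cumsum(sort(v, decreasing = TRUE))
  ## tolerance guards the fraction == 1 case against summation round-off
  unname(which(cs >= fraction * tot - 1e-9 * tot)[1])
}

#' Spearman correlation of circRNAs with their overlapping genes
#'
#' One record per (circRNA, overlapping gene) pair that is computable: at
#' least `min_samples` shared samples and both expression vectors
#' non-constant. Rho uses average ranks for ties. Non-computable pairs are
#' omitted; their count is returned as attribute `n_noncomputable`.
#'
#' @param circ_m circRNA RPM matrix ([circrna_matrix()]).
#' @param gene_m gene FPKM matrix ([gene_matrix()]).
#' @param annotations [categorize_circrna()] output linking circRNAs to genes.
#' @param min_samples minimum shared samples (default 3).
#' @return `data.table`: `circ_id`, `gene_id`, `rho`, `n_samples`; attribute
#'   `n_noncomputable`.
#' @export
correlate <- function(circ_m, gene_m, annotations, min_samples = 3L) {
  annotations <- as.data.table(annotations)
  shared <- intersect(colnames(circ_m), colnames(gene_m))
  pairs <- circ_gene_pairs(annotations)
  pairs <- pairs[circ_id %in% rownames(circ_m) & gene_id %in% rownames(gene_m)]
  out <- vector("list", nrow(pairs))
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (length(shared) < min_samples) { skipped <- skipped + 1L; next }
    x <- circ_m[pairs$circ_id[i], shared]
    y <- gene_m[pairs$gene_id[i], shared]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
      skipped <- skipped + 1L
      next
    }
    out[[i]] <- data.table(circ_id = pairs$circ_id[i], gene_id = pairs$gene_id[i],
                           rho = cor(x, y, method = "spearman"),
                           n_samples = length(shared))
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(circ_id = character(), gene_id = character(),
                      rho = numeric(), n_samples = integer())
  setattr(res, "n_noncomputable", skipped)
  res[]
}
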