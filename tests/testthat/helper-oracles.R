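## Independent oracles and small in-memory data builders used across tests.
## These deliberately avoid the package's own code paths: linear scans,
## exhaustive enumeration and hand-rolled rank arithmetic.

suppressMessages(library(data.table))

## random harmonized evidence table: n junctions, random method/sample
## evidence and counts; used for property-style tests
random_evidence <- function(n, n_samples = 3L, max_count = 6L) {
  samples <- sprintf("s%d", seq_len(n_samples))
  rows <- lapply(seq_len(n), function(i) {
    meths <- sample(CIRC_METHODS, sample(1:4, 1L))
    smps <- sample(samples, sample(1:n_samples, 1L))
    grid <- CJ(method = meths, sample_id = smps)
    ## not every (sample, method) pair has evidence
    grid <- grid[runif(.N) < 0.8]
    if (nrow(grid) == 0L) grid <- CJ(method = meths[1], sample_id = smps[1])
    grid[, `:=`(chrom = as.character(sample(1:3, 1L)),
                start = i * 1000L, end = i * 1000L + sample(100:5000, 1L),
                strand = sample(c("+", "-"), 1L),
                read_count = sample(1:max_count, nrow(grid), replace = TRUE))]
    grid
  })
  ev <- rbindlist(rows)
  setcolorder(ev, c("chrom", "start", "end", "strand", "sample_id", "method",
                    "read_count"))
  setorder(ev, chrom, start, end, sample_id, method)
  class(ev) <- c("circ_evidence", class(ev))
  ev
}

## brute-force reliable-set rule: set logic written independently of
## select_reliable()
oracle_reliable_keys <- function(ev, min_methods = 2L, min_reads = 2L,
                                 methods = CIRC_METHODS) {
  ev <- as.data.table(ev)[method %in% methods]
  keys <- unique(ev[, paste(chrom, start, end)])
  keep <- character()
  for (k in keys) {
    sub <- ev[paste(chrom, start, end) == k]
    if (length(unique(sub$method)) >= min_methods &&
        max(sub$read_count) >= min_reads)
      keep <- c(keep, k)
  }
  keep
}

## hand-built toy annotation used by annotation unit tests:
##   gA (+, chr "t"): exons [100,200) and [400,500), span [100,500)
##   gB (-, chr "t"): exons [450,600) and [800,900)  (overlaps gA's tail)
##   gC (+, chr "t"): single exon [5000,5100) (small, isolated)
toy_genes <- function() {
  dt <- data.table(
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    gene_name = c("GENEA", "GENEA", "GENEB", "GENEB", "GENEC"),
    chrom = "t", strand = c("+", "+", "-", "-", "+"),
    start = c(100L, 400L, 450L, 800L, 5000L),
    end = c(200L, 500L, 600L, 900L, 5100L)
  )
  class(dt) <- c("gene_models", class(dt))
  dt
}

## linear-scan classification of a single base: the interval-index oracle
scan_classify <- function(genes, qchrom, pos) {
  genes <- as.data.table(genes)
  in_exon <- genes[chrom == qchrom & start <= pos & pos < end, unique(gene_id)]
  spans <- genes[, .(s = min(start), e = max(end), chrom = chrom[1]),
                 by = gene_id]
  in_gene <- spans[chrom == qchrom & s <= pos & pos < e, unique(gene_id)]
  cls <- if (length(in_exon)) "exonic"
         else if (length(in_gene)) "intronic" else "intergenic"
  list(class = cls, genes = sort(in_gene))
}

## average ranks computed from first principles (positions in sorted order)
avg_ranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  pos <- seq_along(x)
  for (v in unique(x)) r[x == v] <- mean(pos[x[o] == v])
  r
}

## Spearman rho as Pearson on hand-computed average ranks
spearman_oracle <- function(x, y) {
  rx <- avg_ranks(x); ry <- avg_ranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

## exhaustive prefix-sum oracle for cumulative_share
prefix_share_oracle <- function(v, fraction) {
  sv <- sort(v, decreasing = TRUE)
  for (k in seq_along(sv)) {
    if (sum(sv[seq_len(k)]) >= fraction * sum(v) - 1e-12 * sum(v)) return(k)
  }
  length(sv)
}

## P(at least k of the four methods detect), by enumeration of all 2^4
## detection patterns
detection_prob_oracle <- function(sens, k = 2L) {
  p <- 0
  for (mask in 0:15) {
    bits <- as.integer(intToBits(mask)[1:4])
    if (sum(bits) >= k)
      p <- p + prod(ifelse(bits == 1L, sens, 1 - sens))
  }
  p
}

## minimal GTF writer for hand-built annotations (1-based inclusive)
write_toy_gtf <- function(genes, path) {
  genes <- as.data.table(genes)
  writeLines(sprintf(
    "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id,
    genes$gene_name), path)
  path
}
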