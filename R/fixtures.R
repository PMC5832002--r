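## Synthetic detector-output generator.
##
## Plants a ground-truth circRNA set over a toy gene annotation and emits
## per-sample, per-method detector files in their native dialects, the GTF,
## per-sample gene expression tables and a machine-readable truth table. The
## generator and the annotation module are independent implementations of the
## category rules, so planted categories double as an oracle for the
## annotator. All sampling is driven by a single seed; a fixed seed yields
## byte-identical output trees.

#' Specification of a synthetic fixture
#'
#' Defaults emulate a four-sample, four-method study: every method sees every
#' junction (noiseless) unless per-method `sensitivity` is lowered;
#' `fp_rate` plants method-private spurious junctions (expected count per
#' true junction) in gene-free regions. Read counts per (circRNA, sample)
#' follow a negative binomial (`read_mean`, `read_dispersion`), zero-inflated
#' in practice; one sample per junction is bumped to at least 2 reads so
#' every planted circRNA is expressed at the default reliable-set read
#' threshold.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes in the toy annotation.
#' @param n_circrnas number of planted circRNAs.
#' @param n_samples number of samples.
#' @param sensitivity named per-method detection probabilities in \[0, 1\].
#' @param fp_rate named per-method expected spurious junctions per true one.
#' @param read_mean,read_dispersion negative-binomial mean and size of
#'   per-sample back-splice read counts.
#' @param category_mix proportions of exonic/intronic/intergenic planted
#'   circRNAs (must sum to 1).
#' @param total_mapped_reads per-sample total mapped reads (recycled).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 60L, n_circrnas = 100L,
                         n_samples = 4L,
                         sensitivity = setNames(rep(1, 4), CIRC_METHODS),
                         fp_rate = setNames(rep(0, 4), CIRC_METHODS),
                         read_mean = 5, read_dispersion = 2,
                         category_mix = c(exonic = 0.90, intronic = 0.05,
                                          intergenic = 0.05),
                         total_mapped_reads = 1e6) {
  sensitivity <- sensitivity[CIRC_METHODS]
  fp_rate <- fp_rate[CIRC_METHODS]
  if (anyNA(sensitivity) || any(sensitivity < 0 | sensitivity > 1))
    stop("sensitivity must name all four methods with values in [0, 1]",
         call. = FALSE)
  if (anyNA(fp_rate) || any(fp_rate < 0))
    stop("fp_rate must name all four methods with values >= 0", call. = FALSE)
  if (abs(sum(category_mix) - 1) > 1e-8 || any(category_mix < 0) ||
      !setequal(names(category_mix), c("exonic", "intronic", "intergenic")))
    stop("category_mix must be proportions over exonic/intronic/intergenic summing to 1",
         call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_circrnas = as.integer(n_circrnas), n_samples = as.integer(n_samples),
    sensitivity = sensitivity, fp_rate = fp_rate,
    read_mean = read_mean, read_dispersion = read_dispersion,
    category_mix = category_mix[c("exonic", "intronic", "intergenic")],
    total_mapped_reads = rep_len(total_mapped_reads, n_samples)
  ), class = "fixture_spec")
}

## deterministic toy gene layout: genes laid end to end with wide intergenic
## gaps over four chromosomes; returns exon table + per-gene span table
lay_genes <- function(n_genes) {
  chroms <- as.character(1:4)
  cur <- setNames(rep(10000L, 4), chroms)
  exons <- vector("list", n_genes)
  spans <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    chrom <- chroms[((g - 1L) %% 4L) + 1L]
    gid <- sprintf("G%06d", g)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(2:5, 1L)
    pos <- cur[chrom]
    es <- integer(n_ex); ee <- integer(n_ex)
    for (e in seq_len(n_ex)) {
      es[e] <- pos
      ee[e] <- pos + sample(100:300, 1L)
      pos <- ee[e] + sample(200:500, 1L)   # intron
    }
    exons[[g]] <- data.table(gene_id = gid, gene_name = sprintf("GENE%d", g),
                             chrom = chrom, strand = strand,
                             start = es, end = ee)
    spans[[g]] <- data.table(gene_id = gid, chrom = chrom, strand = strand,
                             gene_start = es[1], gene_end = ee[n_ex])
    cur[chrom] <- ee[n_ex] + sample(5000:10000, 1L)   # intergenic gap
  }
  list(exons = rbindlist(exons), spans = rbindlist(spans),
       chrom_len = cur + 50000L)
}

## plant one circRNA of the requested category; returns (chrom,start,end,strand)
plant_circ <- function(category, exons, spans, chrom_len) {
  if (category == "exonic") {
    gid <- sample(spans$gene_id, 1L)
    ex <- exons[gene_id == gid]
    a <- sample(nrow(ex), 1L); b <- sample(a:nrow(ex), 1L)
    s <- sample(ex$start[a]:(ex$end[a] - 1L), 1L)
    eb <- sample(ex$start[b]:(ex$end[b] - 1L), 1L)
    if (eb <= s) return(NULL)
    c(ex$chrom[1], s, eb + 1L, ex$strand[1])
  } else if (category == "intronic") {
    gid <- sample(spans$gene_id, 1L)
    ex <- exons[gene_id == gid]
    if (nrow(ex) < 2L) return(NULL)
    ## introns: gaps between consecutive exons
    a <- sample(nrow(ex) - 1L, 1L); b <- sample(a:(nrow(ex) - 1L), 1L)
    s <- sample(ex$end[a]:(ex$start[a + 1L] - 1L), 1L)
    eb <- sample(ex$end[b]:(ex$start[b + 1L] - 1L), 1L)
    if (eb <= s) return(NULL)
    c(ex$chrom[1], s, eb + 1L, ex$strand[1])
  } else {
    ## intergenic: both ends inside one gene-free gap on a chromosome
    ch <- sample(names(chrom_len), 1L)
    sp <- spans[chrom == ch]
    setorder(sp, gene_start)
    gap_lo <- c(0L, sp$gene_end)
    gap_hi <- c(sp$gene_start, chrom_len[[ch]])
    wide <- which(gap_hi - gap_lo > 400L)
    k <- wide[sample(length(wide), 1L)]
    lo <- gap_lo[k] + 5L; hi <- gap_hi[k] - 5L
    s <- sample(lo:(hi - 50L), 1L)
    eb <- sample((s + 20L):min(hi - 1L, s + 2000L), 1L)
    c(ch, s, eb + 1L, sample(c("+", "-"), 1L))
  }
}

#' Generate a synthetic fixture directory
#'
#' Writes, under `out_dir`: `annotation.gtf`; one detector file per
#' (sample, method) in the method's native dialect under `<sample>/`;
#' per-sample gene expression tables `<sample>/gene_expression.tsv`;
#' `totals.tsv`; `metadata.tsv` (the run-config sample table); and
#' `truth.tsv` with every planted circRNA, its true category, which methods
#' detected it, and per-sample true read counts.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `truth` (`data.table`), `dir`, and the
#'   sample ids.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- sprintf("sample_%d", seq_len(spec$n_samples))

  layout <- lay_genes(spec$n_genes)
  exons <- layout$exons; spans <- layout$spans

  ## --- GTF (Ensembl flavour, 1-based inclusive) ---
  gtf <- exons[, sprintf(
    "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\"; gene_name \"%s\";",
    chrom, start + 1L, end, strand, gene_id, gene_id, gene_name)]
  writeLines(gtf, file.path(out_dir, "annotation.gtf"))

  ## --- plant circRNAs ---
  n_cat <- round(spec$n_circrnas * spec$category_mix)
  n_cat[1] <- spec$n_circrnas - sum(n_cat[-1])
  cats <- rep(names(n_cat), n_cat)
  planted <- list(); seen <- character()
  for (cat in cats) {
    repeat {
      p <- plant_circ(cat, exons, spans, layout$chrom_len)
      if (is.null(p)) next
      key <- paste(p[1], p[2], p[3])
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    planted[[length(planted) + 1L]] <- data.table(
      chrom = p[1], start = as.integer(p[2]), end = as.integer(p[3]),
      strand = p[4], true_category = cat)
  }
  truth <- rbindlist(planted)

  ## --- per-sample true read counts; one sample bumped to >= 2 reads ---
  counts <- matrix(rnbinom(nrow(truth) * spec$n_samples,
                           mu = spec$read_mean, size = spec$read_dispersion),
                   nrow = nrow(truth))
  top <- max.col(counts, ties.method = "first")
  counts[cbind(seq_len(nrow(truth)), top)] <-
    pmax(counts[cbind(seq_len(nrow(truth)), top)], 2L)
  colnames(counts) <- samples

  ## --- which methods detect each planted junction ---
  det <- sapply(CIRC_METHODS, function(m)
    runif(nrow(truth)) < spec$sensitivity[[m]])
  det <- matrix(det, nrow = nrow(truth), dimnames = list(NULL, CIRC_METHODS))
  truth[, detected_by := apply(det, 1L, function(d)
    paste(CIRC_METHODS[d], collapse = ","))]
  truth[, circ_id := circrna_id(chrom, start, end, strand)]
  for (s in samples) set(truth, j = paste0("count_", s), value = counts[, s])

  ## --- method-private false positives in per-method reserved tail zones ---
  fp <- list()
  for (mi in seq_along(CIRC_METHODS)) {
    m <- CIRC_METHODS[mi]
    n_fp <- rpois(1L, spec$fp_rate[[m]] * nrow(truth))
    if (n_fp == 0L) next
    ch <- as.character(((seq_len(n_fp) - 1L) %% 4L) + 1L)
    zone <- layout$chrom_len[ch] + (mi - 1L) * 100000L
    ## offsets drawn without replacement: starts are unique per method, and
    ## per-method zones beyond the chromosome ends never collide with planted
    ## junctions or with other methods' zones
    s <- unname(zone + as.integer(sample.int(90000L, n_fp)))
    len <- sample(100:1000, n_fp, replace = TRUE)
    fpc <- matrix(rnbinom(n_fp * spec$n_samples, mu = spec$read_mean,
                          size = spec$read_dispersion), nrow = n_fp)
    fpc[fpc[, 1] == 0, 1] <- 1L   # visible in at least one sample
    colnames(fpc) <- samples
    fp[[m]] <- list(dt = data.table(chrom = ch, start = s, end = s + len,
                                    strand = sample(c("+", "-"), n_fp, TRUE)),
                    counts = fpc)
  }

  ## --- emit detector files per (sample, method) ---
  dialects <- default_dialects()
  for (s in samples) {
    sdir <- file.path(out_dir, s)
    dir.create(sdir, showWarnings = FALSE)
    for (m in CIRC_METHODS) {
      keep <- det[, m] & counts[, s] > 0L
      calls <- data.table(
        method = m, sample_id = s,
        chrom = truth$chrom[keep],
        start_native = truth$start[keep] - dialects[[m]]$start_offset,
        end_native = truth$end[keep] - dialects[[m]]$end_offset,
        strand = truth$strand[keep],
        read_count = counts[keep, s]
      )
      if (!is.null(fp[[m]])) {
        fkeep <- fp[[m]]$counts[, s] > 0L
        if (any(fkeep)) {
          calls <- rbind(calls, data.table(
            method = m, sample_id = s,
            chrom = fp[[m]]$dt$chrom[fkeep],
            start_native = fp[[m]]$dt$start[fkeep] - dialects[[m]]$start_offset,
            end_native = fp[[m]]$dt$end[fkeep] - dialects[[m]]$end_offset,
            strand = fp[[m]]$dt$strand[fkeep],
            read_count = fp[[m]]$counts[fkeep, s]
          ))
        }
      }
      setorder(calls, chrom, start_native, end_native)
      write_detector_file(calls, file.path(sdir, paste0(m, ".tsv")), m)
    }
  }

  ## --- per-sample gene expression tables ---
  glen <- exons[, .(len = sum(end - start)), by = gene_id]
  for (si in seq_along(samples)) {
    s <- samples[si]
    raw <- rnbinom(nrow(glen), mu = 200, size = 5)
    fpkm <- round(raw / (glen$len / 1e3) / (spec$total_mapped_reads[si] / 1e6), 4)
    fwrite(data.table(gene_id = glen$gene_id, FPKM = fpkm, raw_count = raw),
           file.path(out_dir, s, "gene_expression.tsv"), sep = "\t")
  }
  fwrite(data.table(sample_id = samples,
                    total_mapped_reads = spec$total_mapped_reads),
         file.path(out_dir, "totals.tsv"), sep = "\t")

  ## --- metadata table for run_project() ---
  meta <- data.table(sample_id = samples,
                     group = rep(c("groupA", "groupB"),
                                 length.out = length(samples)))
  for (m in CIRC_METHODS)
    meta[[m]] <- file.path(samples, paste0(m, ".tsv"))
  meta[["expression"]] <- file.path(samples, "gene_expression.tsv")
  meta[["total_mapped_reads"]] <- spec$total_mapped_reads
  fwrite(meta, file.path(out_dir, "metadata.tsv"), sep = "\t")

  setcolorder(truth, c("circ_id", "chrom", "start", "end", "strand",
                       "true_category", "detected_by"))
  fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  invisible(list(truth = truth[], dir = out_dir, samples = samples))
}

#' Score pipeline output against the planted truth
#'
#' @param reliable reliable-set junction table ([circ_junctions()] of the
#'   [select_reliable()] output) or `circ_evidence` table.
#' @param truth truth table from [generate_fixture()] (or read from
#'   `truth.tsv`).
#' @return list: `sensitivity` (fraction of planted circRNAs recovered) and
#'   `false_discovery_count` (reliable junctions absent from the truth).
#' @export
score_against_truth <- function(reliable, truth) {
  reliable <- as.data.table(reliable)
  truth <- as.data.table(truth)
  rkey <- unique(reliable[, paste(chrom, start, end)])
  tkey <- truth[, paste(chrom, start, end)]
  if (anyDuplicated(tkey)) stop("duplicate junctions in truth table", call. = FALSE)
  list(sensitivity = mean(tkey %in% rkey),
       false_discovery_count = sum(!rkey %in% tkey))
}
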