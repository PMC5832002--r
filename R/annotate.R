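## Classification of back-splice junctions against gene models.
##
## Each junction end is a single boundary base (start-side base = internal
## start; end-side base = internal end - 1). An end is "exonic" if it lies
## inside at least one annotated exon, "intronic" if inside at least one gene
## span but no exon, "intergenic" otherwise. Overlap ignores strand by
## default: circRNAs are routinely annotated to genes on either strand.

#' Build an interval-queryable index over exons and gene spans
#'
#' Two stabbing-query layers: exon intervals mapped to their gene, and whole
#' gene spans (min exon start to max exon end per gene).
#'
#' @param genes a `gene_models` table from [parse_gtf()].
#' @return an `exon_index` list with `GRanges` layers `exons` and `genes`,
#'   plus the gene_id -> gene_name map.
#' @export
build_exon_index <- function(genes) {
  genes <- as.data.table(genes)
  if (nrow(genes) == 0L) {
    e <- GenomicRanges::GRanges()
    return(structure(list(exons = e, genes = e,
                          gene_names = character()), class = "exon_index"))
  }
  exons <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    gene_id = genes$gene_id
  )
  spans <- genes[, .(chrom = chrom[1], start = min(start), end = max(end),
                     gene_name = gene_name[1]), by = gene_id]
  gspan <- GenomicRanges::GRanges(
    seqnames = spans$chrom,
    ranges = IRanges::IRanges(start = spans$start + 1L, end = spans$end),
    gene_id = spans$gene_id
  )
  structure(list(exons = exons, genes = gspan,
                 gene_names = setNames(spans$gene_name, spans$gene_id)),
            class = "exon_index")
}

## genes whose layer intervals contain the given 1-based positions;
## returns list of character vectors, one per query
stab_genes <- function(layer, chrom, pos1) {
  if (length(layer) == 0L)
    return(rep(list(character()), length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos1, pos1))
  hits <- GenomicRanges::findOverlaps(q, layer, ignore.strand = TRUE)
  res <- rep(list(character()), length(chrom))
  if (length(hits)) {
    gid <- split(layer$gene_id[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    res[as.integer(names(gid))] <- lapply(gid, function(g) sort(unique(g)))
  }
  res
}

#' Classify a single genomic position against the annotation
#'
#' @param chrom chromosome name.
#' @param pos position of the base in the internal 0-based convention (the
#'   base occupying `[pos, pos + 1)`).
#' @param idx an `exon_index`.
#' @return list with `class` (`"exonic"`, `"intronic"` or `"intergenic"`) and
#'   `genes` (character vector of gene ids whose span contains the base).
#' @export
classify_end <- function(chrom, pos, idx) {
  stopifnot(inherits(idx, "exon_index"))
  p1 <- as.integer(pos) + 1L
  eg <- stab_genes(idx$exons, chrom, p1)[[1]]
  gg <- stab_genes(idx$genes, chrom, p1)[[1]]
  cls <- if (length(eg)) "exonic" else if (length(gg)) "intronic" else "intergenic"
  list(class = cls, genes = gg)
}

#' Annotate circRNAs with category labels and overlapping genes
#'
#' Both back-splice ends are classified (see [classify_end()]) and combined:
#' both ends exonic -> `"exonic"`; both ends within gene spans but at least
#' one non-exonic -> `"intronic"`; both ends outside genes -> `"intergenic"`;
#' mixed end classes give a `"|"`-joined composite of the distinct end
#' classes. When a gene lies strictly inside the junction span without
#' containing either end, the part `"intergenic spanning gene"` is appended
#' and the spanned genes join the gene list.
#'
#' @param junctions junction table from [circ_junctions()] (or any table with
#'   `circ_id`, `chrom`, `start`, `end`).
#' @param idx an `exon_index` from [build_exon_index()].
#' @return `data.table`: `circ_id`, `category`, `gene_ids` and `gene_names`
#'   (comma-joined, empty string when intergenic).
#' @export
categorize_circrna <- function(junctions, idx) {
  stopifnot(inherits(idx, "exon_index"))
  junctions <- as.data.table(junctions)
  n <- nrow(junctions)
  if (n == 0L)
    return(data.table(circ_id = character(), category = character(),
                      gene_ids = character(), gene_names = character()))
  sp1 <- junctions$start + 1L        # start-side boundary base, 1-based
  ep1 <- junctions$end               # end-side boundary base (internal end-1), 1-based
  ex_s <- stab_genes(idx$exons, junctions$chrom, sp1)
  ex_e <- stab_genes(idx$exons, junctions$chrom, ep1)
  gn_s <- stab_genes(idx$genes, junctions$chrom, sp1)
  gn_e <- stab_genes(idx$genes, junctions$chrom, ep1)

  ## genes strictly inside the junction span (not containing either end)
  spanned <- rep(list(character()), n)
  if (length(idx$genes)) {
    q <- GenomicRanges::GRanges(junctions$chrom,
                                IRanges::IRanges(sp1, pmax(sp1, ep1)))
    hits <- GenomicRanges::findOverlaps(q, idx$genes, type = "any",
                                        ignore.strand = TRUE)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      inside <- GenomicRanges::start(idx$genes)[sh] > sp1[qh] &
                GenomicRanges::end(idx$genes)[sh] < ep1[qh]
      if (any(inside)) {
        gid <- split(idx$genes$gene_id[sh[inside]], qh[inside])
        spanned[as.integer(names(gid))] <- lapply(gid, function(g) sort(unique(g)))
      }
    }
  }

  cls1 <- ifelse(lengths(ex_s) > 0, "exonic",
                 ifelse(lengths(gn_s) > 0, "intronic", "intergenic"))
  cls2 <- ifelse(lengths(ex_e) > 0, "exonic",
                 ifelse(lengths(gn_e) > 0, "intronic", "intergenic"))
  lvl <- c("exonic", "intronic", "intergenic")
  category <- character(n); gene_ids <- character(n); gene_names <- character(n)
  for (i in seq_len(n)) {
    parts <- lvl[lvl %in% unique(c(cls1[i], cls2[i]))]
    if (length(parts) == 2L && identical(parts, c("exonic", "intronic")))
      parts <- "intronic"  # both ends intra-gene, not both exonic
    lab <- paste(parts, collapse = "|")
    sp <- setdiff(spanned[[i]], c(gn_s[[i]], gn_e[[i]]))
    if (length(sp)) lab <- paste(lab, "intergenic spanning gene", sep = "|")
    category[i] <- lab
    g <- sort(unique(c(gn_s[[i]], gn_e[[i]], sp)))
    gene_ids[i] <- paste(g, collapse = ",")
    gene_names[i] <- paste(unname(idx$gene_names[g]), collapse = ",")
  }
  data.table(circ_id = junctions$circ_id, category = category,
             gene_ids = gene_ids, gene_names = gene_names)
}

## expand comma-joined gene_ids into one (circ_id, gene_id) row per pair
circ_gene_pairs <- function(annotations) {
  annotations <- as.data.table(annotations)[nzchar(gene_ids)]
  if (nrow(annotations) == 0L)
    return(data.table(circ_id = character(), gene_id = character()))
  annotations[, .(gene_id = unlist(strsplit(gene_ids, ",", fixed = TRUE))),
              by = circ_id]
}

#' Number of circRNAs per gene and its frequency distribution
#'
#' A circRNA overlapping several genes increments each of them. Genes with no
#' circRNA are omitted.
#'
#' @param annotations output of [categorize_circrna()].
#' @return list with `per_gene` (`data.table`: `gene_id`, `n_circrnas`) and
#'   `distribution` (`data.table`: `n_circrnas`, `n_genes`).
#' @export
circrnas_per_gene <- function(annotations) {
  g <- circ_gene_pairs(annotations)
  if (nrow(g) == 0L)
    return(list(per_gene = data.table(gene_id = character(),
                                      n_circrnas = integer()),
                distribution = data.table(n_circrnas = integer(),
                                          n_genes = integer())))
  per_gene <- g[, .(n_circrnas = uniqueN(circ_id)), by = gene_id]
  setorder(per_gene, -n_circrnas, gene_id)
  distribution <- per_gene[, .(n_genes = .N), by = n_circrnas]
  setorder(distribution, n_circrnas)
  list(per_gene = per_gene[], distribution = distribution[])
}
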