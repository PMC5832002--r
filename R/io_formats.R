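## Readers and writers for the four detector output dialects, GTF gene models,
## expression tables, and the harmonized circRNA tables. The canonical dialect
## of each tool is fixed in inst/FORMATS.md; parsers and the fixture writers
## must agree bit-exactly, so both live here.

#' Coordinate-convention specifications for the four detector dialects
#'
#' Each detector reports back-splice coordinates in its own convention. The
#' package-internal convention is 0-based half-open (BED-like). A dialect spec
#' gives, per method, the offsets added to the native start/end to reach the
#' internal convention, so a single conversion site exists per dialect.
#'
#' Defaults: CIRI is 1-based inclusive (`start_offset = -1L, end_offset = 0L`);
#' find_circ, CIRCexplorer and testrealign are 0-based half-open (identity).
#' The testrealign entry is deliberately overridable: whether its coordinates
#' need shifting relative to the other tools is a property of the tool version,
#' not of this package.
#'
#' @param ... named per-method overrides, each a list with `start_offset`
#'   and `end_offset` integers, e.g.
#'   `default_dialects(testrealign = list(start_offset = 1L, end_offset = 1L))`.
#' @return named list of per-method offset specs.
#' @export
default_dialects <- function(...) {
  spec <- list(
    circexplorer = list(start_offset = 0L, end_offset = 0L),
    ciri         = list(start_offset = -1L, end_offset = 0L),
    findcirc     = list(start_offset = 0L, end_offset = 0L),
    testrealign  = list(start_offset = 0L, end_offset = 0L)
  )
  over <- list(...)
  for (m in names(over)) {
    if (!m %in% CIRC_METHODS)
      stop("unknown method in dialect override: ", m, call. = FALSE)
    stopifnot(is.numeric(over[[m]]$start_offset), is.numeric(over[[m]]$end_offset))
    spec[[m]] <- lapply(over[[m]], as.integer)
  }
  spec
}

empty_calls <- function() {
  data.table(
    method = character(), sample_id = character(), chrom = character(),
    start_native = integer(), end_native = integer(), strand = character(),
    read_count = integer()
  )
}

parse_fail <- function(path, lineno, msg, lenient) {
  full <- sprintf("%s: line %d: %s", path, lineno, msg)
  if (lenient) {
    warning(full, call. = FALSE)
    FALSE
  } else {
    stop(full, call. = FALSE)
  }
}

## field validators shared by all dialect parsers
chk_int <- function(x) grepl("^[0-9]+$", x)
chk_strand <- function(x) x %in% c("+", "-", ".")

#' Parse the native output file of one back-splice detection method
#'
#' Reads one per-sample detector output file in the tool's canonical dialect
#' (see `system.file("FORMATS.md", package = "circonsensus")`) and returns one
#' back-splice call per record, in the method's native coordinate convention.
#' Malformed lines are an error naming the offending line number; with
#' `lenient = TRUE` they are skipped with a warning instead. An empty file
#' yields an empty table, not an error.
#'
#' @param path path to the detector output file.
#' @param method one of `r paste0('"', CIRC_METHODS, '"', collapse = ", ")`.
#' @param sample_id sample identifier attached to every call.
#' @param lenient if TRUE, downgrade malformed-line errors to warnings.
#' @return a `data.table` with columns `method`, `sample_id`, `chrom`,
#'   `start_native`, `end_native`, `strand` (`+`, `-` or `.`), `read_count`.
#' @export
parse_detector_output <- function(path, method, sample_id, lenient = FALSE) {
  if (!is.character(method) || length(method) != 1L || !method %in% CIRC_METHODS)
    stop("unknown method: ", paste(method, collapse = ","),
         " (supported: ", paste(CIRC_METHODS, collapse = ", "), ")", call. = FALSE)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  skip <- 0L
  if (method == "ciri") {
    ## CIRI files carry a header line starting with "circRNA_ID"
    if (length(lines) > 0L && startsWith(lines[1L], "circRNA_ID")) skip <- 1L
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (i <= skip || !nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rec <- switch(method,
      ciri = {
        if (length(f) < 6L) { parse_fail(path, i, "expected 6 fields", lenient); NULL }
        else if (!chk_int(f[3]) || !chk_int(f[4]))
          { parse_fail(path, i, "non-integer coordinates", lenient); NULL }
        else if (!chk_int(f[5]))
          { parse_fail(path, i, "non-integer junction_reads", lenient); NULL }
        else if (!chk_strand(f[6]))
          { parse_fail(path, i, paste0("bad strand '", f[6], "'"), lenient); NULL }
        else list(f[2], as.integer(f[3]), as.integer(f[4]), f[6], as.integer(f[5]))
      },
      findcirc = {
        if (length(f) < 6L) { parse_fail(path, i, "expected 6 fields", lenient); NULL }
        else if (!chk_int(f[2]) || !chk_int(f[3]))
          { parse_fail(path, i, "non-integer coordinates", lenient); NULL }
        else if (!chk_int(f[5]))
          { parse_fail(path, i, "non-integer n_reads", lenient); NULL }
        else if (!chk_strand(f[6]))
          { parse_fail(path, i, paste0("bad strand '", f[6], "'"), lenient); NULL }
        else list(f[1], as.integer(f[2]), as.integer(f[3]), f[6], as.integer(f[5]))
      },
      circexplorer = {
        if (length(f) < 13L) { parse_fail(path, i, "expected 13 fields", lenient); NULL }
        else if (!chk_int(f[2]) || !chk_int(f[3]))
          { parse_fail(path, i, "non-integer coordinates", lenient); NULL }
        else if (!chk_int(f[13]))
          { parse_fail(path, i, "non-integer readNumber", lenient); NULL }
        else if (!chk_strand(f[6]))
          { parse_fail(path, i, paste0("bad strand '", f[6], "'"), lenient); NULL }
        else list(f[1], as.integer(f[2]), as.integer(f[3]), f[6], as.integer(f[13]))
      },
      testrealign = {
        if (length(f) < 6L) { parse_fail(path, i, "expected 6 fields", lenient); NULL }
        else if (!f[4] %in% c("C", "N"))
          { parse_fail(path, i, paste0("bad event type '", f[4], "'"), lenient); NULL }
        else if (f[4] == "N") NULL   # linear splice event: not a back-splice
        else if (!chk_int(f[2]) || !chk_int(f[3]))
          { parse_fail(path, i, "non-integer coordinates", lenient); NULL }
        else if (!chk_int(f[5]))
          { parse_fail(path, i, "non-integer n_reads", lenient); NULL }
        else if (!chk_strand(f[6]))
          { parse_fail(path, i, paste0("bad strand '", f[6], "'"), lenient); NULL }
        else list(f[1], as.integer(f[2]), as.integer(f[3]), f[6], as.integer(f[5]))
      }
    )
    if (!is.null(rec)) {
      if (rec[[2]] > rec[[3]]) {
        parse_fail(path, i, sprintf("start (%d) > end (%d)", rec[[2]], rec[[3]]), lenient)
        next
      }
      recs[[i]] <- data.table(
        method = method, sample_id = sample_id, chrom = rec[[1]],
        start_native = rec[[2]], end_native = rec[[3]],
        strand = rec[[4]], read_count = rec[[5]]
      )
    }
  }
  out <- rbindlist(recs)
  if (nrow(out) == 0L) return(empty_calls())
  out[]
}

#' Write back-splice calls in a detector's native dialect
#'
#' The exact inverse of [parse_detector_output()]: used by the fixture
#' generator to emit synthetic detector files. Calls must carry native
#' coordinates (`start_native`, `end_native`).
#'
#' @param calls a calls `data.table` as returned by [parse_detector_output()].
#' @param path output file path.
#' @param method dialect to write.
#' @return `path`, invisibly.
#' @export
write_detector_file <- function(calls, path, method) {
  if (!method %in% CIRC_METHODS) stop("unknown method: ", method, call. = FALSE)
  calls <- as.data.table(calls)
  n <- nrow(calls)
  lines <- switch(method,
    ciri = c(
      paste("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
            "junction_reads", "strand", sep = "\t"),
      if (n) sprintf("%s:%d|%d\t%s\t%d\t%d\t%d\t%s",
                     calls$chrom, calls$start_native, calls$end_native,
                     calls$chrom, calls$start_native, calls$end_native,
                     calls$read_count, calls$strand)
    ),
    findcirc = if (n) sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                              calls$chrom, calls$start_native, calls$end_native,
                              "circ_site", calls$read_count, calls$strand)
               else character(),
    circexplorer = if (n) sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s\t%d",
      calls$chrom, calls$start_native, calls$end_native, "circular_RNA", 0L,
      calls$strand, calls$start_native, calls$end_native, "0,0,0", 1L,
      calls$end_native - calls$start_native, "0", calls$read_count)
      else character(),
    testrealign = if (n) sprintf("%s\t%d\t%d\tC\t%d\t%s",
                                 calls$chrom, calls$start_native, calls$end_native,
                                 calls$read_count, calls$strand)
                  else character()
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse gene models from a GTF annotation
#'
#' Reads exon features from an Ensembl-flavour GTF (1-based inclusive) and
#' returns one row per unique (gene, exon interval), in the internal 0-based
#' half-open convention. Exons shared by several transcripts of a gene are
#' stored once. Rows are sorted by gene then ascending exon start regardless
#' of strand.
#'
#' @param path path to a GTF file.
#' @return a `data.table` with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `start`, `end` (internal convention), class `gene_models`.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) {
    warning("no exon features in ", path, call. = FALSE)
    out <- data.table(gene_id = character(), gene_name = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer())
    setattr(out, "class", c("gene_models", class(out)))
    return(out)
  }
  gid <- S4Vectors::mcols(ex)$gene_id
  if (is.null(gid) || anyNA(gid))
    stop("exon feature without gene_id attribute in ", path, call. = FALSE)
  gname <- S4Vectors::mcols(ex)$gene_name
  if (is.null(gname)) gname <- gid
  gname[is.na(gname)] <- gid[is.na(gname)]
  out <- data.table(
    gene_id = gid, gene_name = gname,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(ex)
  )
  out <- unique(out, by = c("gene_id", "start", "end"))
  setorder(out, gene_id, start, end)
  setattr(out, "class", c("gene_models", class(out)))
  out[]
}

#' Parse a per-sample gene expression table
#'
#' Tab-separated with a header naming the gene id, FPKM and raw count columns
#' (`gene_id`/`tracking_id`, `FPKM`, `raw_count`/`count`; case-insensitive).
#'
#' @param path path to the expression table.
#' @param total_mapped_reads total mapped reads of the sample (> 0).
#' @param sample_id sample identifier.
#' @return list with `sample_id`, `expr` (`data.table`: `gene_id`, `FPKM`,
#'   `raw_count`) and `total_mapped_reads`; class `sample_expression`.
#' @export
parse_expression_table <- function(path, total_mapped_reads, sample_id = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!is.numeric(total_mapped_reads) || length(total_mapped_reads) != 1L ||
      is.na(total_mapped_reads) || total_mapped_reads <= 0)
    stop("total_mapped_reads must be a positive number", call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  pick <- function(cands) {
    hit <- which(tolower(names(dt)) %in% cands)
    if (length(hit) == 0L)
      stop(path, ": header must name a ", cands[1], " column", call. = FALSE)
    hit[1]
  }
  gi <- pick(c("gene_id", "tracking_id"))
  fp <- pick("fpkm")
  rc <- pick(c("raw_count", "count"))
  expr <- data.table(
    gene_id = dt[[gi]],
    FPKM = suppressWarnings(as.numeric(dt[[fp]])),
    raw_count = suppressWarnings(as.integer(dt[[rc]]))
  )
  if (anyNA(expr$FPKM) || anyNA(expr$raw_count))
    stop(path, ": non-numeric FPKM or count value", call. = FALSE)
  if (any(expr$FPKM < 0) || any(expr$raw_count < 0))
    stop(path, ": negative FPKM or count", call. = FALSE)
  if (anyDuplicated(expr$gene_id))
    stop(path, ": duplicated gene id: ",
         expr$gene_id[anyDuplicated(expr$gene_id)], call. = FALSE)
  structure(
    list(sample_id = sample_id, expr = expr[],
         total_mapped_reads = as.numeric(total_mapped_reads)),
    class = "sample_expression"
  )
}

#' Write the harmonized circRNA table (TSV + BED6 companion)
#'
#' One row per circRNA with its display ID (see [circrna_id()]); a 6-column
#' BED companion is written next to the TSV with the `.bed` extension.
#'
#' @param junctions junction-level table from [circ_junctions()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_circrna_table <- function(junctions, path) {
  junctions <- as.data.table(junctions)
  cols <- c("circ_id", "chrom", "start", "end", "strand",
            "n_methods", "n_samples", "total_reads", "max_reads")
  keep <- intersect(cols, names(junctions))
  fwrite(junctions[, keep, with = FALSE], path, sep = "\t")
  bed <- sub("\\.[^.]*$", "", path)
  bed <- paste0(bed, ".bed")
  if (nrow(junctions)) {
    bedlines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                        junctions$chrom, junctions$start, junctions$end,
                        junctions$circ_id,
                        pmin(junctions$total_reads, 1000L),
                        junctions$strand)
  } else bedlines <- character()
  writeLines(bedlines, bed)
  invisible(path)
}

#' Read back a harmonized circRNA table written by [write_circrna_table()]
#' @param path TSV path.
#' @return `data.table` with the written columns.
#' @export
read_circrna_table <- function(path) {
  fread(path, sep = "\t", header = TRUE,
        colClasses = list(character = c("circ_id", "chrom", "strand")))
}
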