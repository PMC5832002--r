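## Conversion of per-method native calls into one back-splice identity space.
##
## The junction key is strandless (chrom, start, end) in the internal 0-based
## half-open convention; matching across methods is exact, with systematic
## convention differences absorbed by the per-dialect offsets. The strand
## attached to a junction is the majority strand over its evidence entries
## (ties -> "."), since detectors occasionally disagree and a stranded key
## would double-count the same junction.

#' Harmonize native back-splice calls into circRNA evidence
#'
#' Converts each call's native coordinates to the internal 0-based half-open
#' convention using the per-method dialect offsets, then merges calls mapping
#' to the same (chrom, start, end): read counts from the same (sample, method)
#' for the same junction are summed; evidence from different samples/methods
#' is kept as separate rows. Zero-read entries are dropped (absence of
#' evidence is not stored).
#'
#' @param calls calls table from [parse_detector_output()] (rows from several
#'   files may be concatenated with `rbind`).
#' @param dialects per-method offset spec, see [default_dialects()].
#' @return a `circ_evidence` `data.table`, one row per
#'   (junction, sample, method) with columns `chrom`, `start`, `end`,
#'   `strand` (majority per junction), `sample_id`, `method`, `read_count`,
#'   sorted by (chrom, start, end).
#' @export
harmonize_calls <- function(calls, dialects = default_dialects()) {
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L) {
    ev <- data.table(chrom = character(), start = integer(), end = integer(),
                     strand = character(), sample_id = character(),
                     method = character(), read_count = integer())
    setattr(ev, "class", c("circ_evidence", class(ev)))
    return(ev)
  }
  miss <- setdiff(unique(calls$method), names(dialects))
  if (length(miss))
    stop("no dialect spec for method(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(calls$start_native > calls$end_native))
    stop("internal error: call with start_native > end_native survived parsing",
         call. = FALSE)
  so <- vapply(dialects, `[[`, integer(1), "start_offset")
  eo <- vapply(dialects, `[[`, integer(1), "end_offset")
  ev <- calls[, .(
    chrom, start = start_native + so[method], end = end_native + eo[method],
    strand, sample_id, method, read_count = as.integer(read_count)
  )]
  ev <- ev[read_count > 0L]
  ev <- ev[, .(read_count = sum(read_count)),
           by = .(chrom, start, end, strand, sample_id, method)]
  ## majority strand per strandless junction key; ties -> "."
  maj <- ev[, {
    tab <- tapply(read_count * 0L + 1L, strand, sum)  # votes: one per evidence row
    tab <- tab[names(tab) != "."]
    if (length(tab) == 0L) s <- "."
    else {
      top <- names(tab)[tab == max(tab)]
      s <- if (length(top) == 1L) top else "."
    }
    .(strand = s)
  }, by = .(chrom, start, end)]
  ev[, strand := NULL]
  ev <- maj[ev, on = c("chrom", "start", "end")]
  ## a strand vote may have produced duplicate (sample, method) rows; re-sum
  ev <- ev[, .(read_count = sum(read_count)),
           by = .(chrom, start, end, strand, sample_id, method)]
  setorder(ev, chrom, start, end, sample_id, method)
  setattr(ev, "class", c("circ_evidence", class(ev)))
  ev[]
}

#' Junction-level view of harmonized evidence
#'
#' Collapses a `circ_evidence` table to one row per circRNA with its display
#' ID, the number of distinct detecting methods and samples, and read-support
#' summaries.
#'
#' @param ev a `circ_evidence` table from [harmonize_calls()].
#' @return `data.table` with one row per junction: `circ_id`, `chrom`,
#'   `start`, `end`, `strand`, `n_methods`, `n_samples`, `total_reads`,
#'   `max_reads`, sorted by (chrom, start, end).
#' @export
circ_junctions <- function(ev) {
  ev <- as.data.table(ev)
  if (nrow(ev) == 0L)
    return(data.table(circ_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_methods = integer(), n_samples = integer(),
                      total_reads = integer(), max_reads = integer()))
  j <- ev[, .(
    n_methods = uniqueN(method), n_samples = uniqueN(sample_id),
    total_reads = sum(read_count), max_reads = max(read_count)
  ), by = .(chrom, start, end, strand)]
  j[, circ_id := circrna_id(chrom, start, end, strand)]
  setorder(j, chrom, start, end)
  setcolorder(j, c("circ_id", "chrom", "start", "end", "strand"))
  j[]
}

#' Display identifier of a circRNA
#'
#' `"chrom:start-end:strand"` with 1-based inclusive display coordinates
#' (internal start + 1, internal end). The chromosome name is passed through
#' untouched: it carries a `chr` prefix iff the input annotation did.
#'
#' @param chrom,start,end,strand vectors describing junctions in the internal
#'   0-based half-open convention; strand `.` denotes unknown.
#' @return character vector of IDs.
#' @export
circrna_id <- function(chrom, start, end, strand = ".") {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start) + 1L, as.integer(end), strand)
}

#' Parse a circRNA display ID back to its internal-coordinate key
#'
#' Inverse of [circrna_id()].
#'
#' @param id character vector of IDs like `"11:33286413-33287511:+"`.
#' @return `data.table` with `chrom`, `start`, `end`, `strand` (internal
#'   convention).
#' @export
parse_circrna_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+):([+.-])$", id))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("malformed circRNA id: ", id[bad][1], call. = FALSE)
  data.table(
    chrom = vapply(m, `[[`, character(1), 2L),
    start = as.integer(vapply(m, `[[`, character(1), 3L)) - 1L,
    end = as.integer(vapply(m, `[[`, character(1), 4L)),
    strand = vapply(m, `[[`, character(1), 5L)
  )
}
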