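## The reliable-circRNA selection rule and method-agreement statistics.
##
## Default rule: a circRNA is "reliable" when detected by at least two of the
## enabled methods and supported by at least two back-splice reads. The read
## threshold applies to the maximum read count over (sample, method) evidence
## entries, so support is never inflated by summing correlated estimates of
## the same molecules across methods; alternative support statistics are
## available for sensitivity analysis.

#' Configuration of the reliable-circRNA selection rule
#'
#' @param min_methods minimum number of distinct enabled methods that must
#'   detect a circRNA (default 2).
#' @param min_reads minimum read support under `support_statistic` (default 2).
#' @param methods_enabled subset of [CIRC_METHODS] considered (default all
#'   four).
#' @param scope `"pooled"`: method agreement counted across all samples;
#'   `"per_sample"`: agreement must occur within at least one single sample.
#' @param support_statistic how per-(sample, method) read counts are reduced
#'   before applying `min_reads`: `"max"` (default), `"sum_over_methods"`
#'   (max over samples of the per-sample sum across methods) or
#'   `"sum_over_samples"` (max over methods of the per-method sum across
#'   samples).
#' @return a `consensus_config` list.
#' @export
consensus_config <- function(min_methods = 2L, min_reads = 2L,
                             methods_enabled = CIRC_METHODS,
                             scope = c("pooled", "per_sample"),
                             support_statistic = c("max", "sum_over_methods",
                                                   "sum_over_samples")) {
  scope <- match.arg(scope)
  support_statistic <- match.arg(support_statistic)
  min_methods <- as.integer(min_methods)
  min_reads <- as.integer(min_reads)
  if (min_methods < 1L || min_reads < 1L)
    stop("min_methods and min_reads must be >= 1", call. = FALSE)
  if (!all(methods_enabled %in% CIRC_METHODS))
    stop("unknown method(s): ",
         paste(setdiff(methods_enabled, CIRC_METHODS), collapse = ", "),
         call. = FALSE)
  if (min_methods > length(methods_enabled))
    stop("min_methods (", min_methods, ") exceeds number of enabled methods (",
         length(methods_enabled), ")", call. = FALSE)
  structure(list(min_methods = min_methods, min_reads = min_reads,
                 methods_enabled = methods_enabled, scope = scope,
                 support_statistic = support_statistic),
            class = "consensus_config")
}

support_stat <- function(ev, statistic) {
  switch(statistic,
    max = ev[, .(support = max(read_count)), by = .(chrom, start, end)],
    sum_over_methods = {
      s <- ev[, .(read_count = sum(read_count)),
              by = .(chrom, start, end, sample_id)]
      s[, .(support = max(read_count)), by = .(chrom, start, end)]
    },
    sum_over_samples = {
      s <- ev[, .(read_count = sum(read_count)),
              by = .(chrom, start, end, method)]
      s[, .(support = max(read_count)), by = .(chrom, start, end)]
    }
  )
}

#' Select the reliable circRNA set
#'
#' Keeps junctions detected by at least `min_methods` distinct enabled
#' methods (across samples under `scope = "pooled"`, within at least one
#' sample under `"per_sample"`) AND supported by at least `min_reads` reads
#' under the configured support statistic. Both conditions are evaluated
#' conjunctively on the same input set. Evidence from disabled methods is
#' ignored entirely. Genomic order is preserved.
#'
#' @param ev a `circ_evidence` table from [harmonize_calls()].
#' @param cfg a [consensus_config()].
#' @return the subset of `ev` rows belonging to reliable junctions.
#' @export
select_reliable <- function(ev, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"))
  ev <- as.data.table(ev)
  ev <- ev[method %in% cfg$methods_enabled]
  if (nrow(ev) == 0L) return(structure(ev, class = class(ev)))
  if (cfg$scope == "pooled") {
    agree <- ev[, .(n_methods = uniqueN(method)), by = .(chrom, start, end)]
  } else {
    per <- ev[, .(n_methods = uniqueN(method)),
              by = .(chrom, start, end, sample_id)]
    agree <- per[, .(n_methods = max(n_methods)), by = .(chrom, start, end)]
  }
  sup <- support_stat(ev, cfg$support_statistic)
  keep <- agree[sup, on = c("chrom", "start", "end")][
    n_methods >= cfg$min_methods & support >= cfg$min_reads,
    .(chrom, start, end)]
  out <- ev[keep, on = c("chrom", "start", "end"), nomatch = NULL]
  setorder(out, chrom, start, end, sample_id, method)
  setattr(out, "class", unique(c("circ_evidence", class(out))))
  out[]
}

#' Per-method detection counts and the n-methods agreement histogram
#'
#' A circRNA counts once per method regardless of how many samples the method
#' detected it in (detection pooled over samples, matching the dataset-wide
#' agreement view).
#'
#' @param ev a `circ_evidence` table.
#' @param methods_enabled methods considered.
#' @return list with `per_method` (named integer vector over
#'   `methods_enabled`), `histogram` (`data.table`: `n_methods`, `n_circrnas`)
#'   and `n_union` (junctions detected by >= 1 enabled method).
#' @export
method_agreement <- function(ev, methods_enabled = CIRC_METHODS) {
  ev <- as.data.table(ev)[method %in% methods_enabled]
  if (nrow(ev) == 0L)
    return(list(per_method = setNames(integer(length(methods_enabled)),
                                      methods_enabled),
                histogram = data.table(n_methods = integer(),
                                       n_circrnas = integer()),
                n_union = 0L))
  det <- unique(ev[, .(chrom, start, end, method)])
  per_method <- setNames(integer(length(methods_enabled)), methods_enabled)
  cnt <- det[, .N, by = method]
  per_method[cnt$method] <- cnt$N
  nm <- det[, .(n_methods = .N), by = .(chrom, start, end)]
  histogram <- nm[, .(n_circrnas = .N), by = n_methods]
  setorder(histogram, n_methods)
  list(per_method = per_method, histogram = histogram[], n_union = nrow(nm))
}

#' Per-sample circRNA counts for the union and the reliable set
#'
#' For each sample, the number of circRNAs with at least one evidence read in
#' that sample, in the whole detected set and in the reliable subset.
#'
#' @param ev union `circ_evidence` table.
#' @param reliable reliable subset, as returned by [select_reliable()].
#' @return `data.table`: `sample_id`, `n_union`, `n_reliable`.
#' @export
per_sample_counts <- function(ev, reliable) {
  ev <- as.data.table(ev); reliable <- as.data.table(reliable)
  u <- ev[read_count > 0L, .(n_union = uniqueN(paste(chrom, start, end))),
          by = sample_id]
  r <- reliable[read_count > 0L,
                .(n_reliable = uniqueN(paste(chrom, start, end))),
                by = sample_id]
  out <- merge(u, r, by = "sample_id", all.x = TRUE)
  out[is.na(n_reliable), n_reliable := 0L]
  setorder(out, sample_id)
  out[]
}
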