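## Aggregate run statistics and their rendering as TSV tables plus a single
## HTML summary. Every number in the rendered output is re-derivable from the
## underlying tables; percentages are always computed from the printed
## integers, never stored independently.

#' Percentage with round-half-up
#'
#' `100 * numerator / denominator`, rounded half-up at `decimals` decimal
#' places (the convention of the report: 17.50 prints as 18, not R's
#' round-half-even 17.5 -> 18 vs 16.5 -> 16).
#'
#' @param numerator,denominator integers; `denominator > 0`.
#' @param decimals digits after the decimal point (default 1).
#' @return rounded percentage.
#' @export
pct <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  if (any(decimals < 0)) stop("decimals must be >= 0", call. = FALSE)
  x <- 100 * numerator / denominator
  s <- 10^decimals
  ## tiny epsilon so values sitting on .5 after binary round-off still go up
  floor(x * s + 0.5 + 1e-9) / s
}

#' Assemble the aggregate statistics of a run
#'
#' @param ev union `circ_evidence` table.
#' @param reliable reliable subset ([select_reliable()]).
#' @param annotations [categorize_circrna()] output for the reliable set.
#' @param correlations [correlate()] output (optional).
#' @param methods_enabled methods used in the run.
#' @param rho_cutoff cutoff for calling a correlation strong (default 0.5).
#' @return a `summary_stats` list: `n_union`, `per_method_counts`,
#'   `agreement_histogram`, `n_reliable`, `per_sample`, `category_counts`,
#'   `n_genes_with_circ`, `circ_per_gene_distribution`, `correlation`.
#' @export
build_summary <- function(ev, reliable, annotations = NULL,
                          correlations = NULL,
                          methods_enabled = CIRC_METHODS, rho_cutoff = 0.5) {
  agr <- method_agreement(ev, methods_enabled)
  rel_j <- circ_junctions(reliable)
  category_counts <- integer()
  n_genes <- 0L
  dist <- data.table(n_circrnas = integer(), n_genes = integer())
  if (!is.null(annotations) && nrow(as.data.table(annotations))) {
    ann <- as.data.table(annotations)
    cc <- ann[, .N, by = category]
    category_counts <- setNames(cc$N, cc$category)
    pg <- circrnas_per_gene(ann)
    n_genes <- nrow(pg$per_gene)
    dist <- pg$distribution
  }
  correlation <- list(n = 0L, mean = NA_real_, median = NA_real_,
                      n_above = 0L, n_below = 0L, n_weak = 0L,
                      rho_cutoff = rho_cutoff)
  if (!is.null(correlations) && nrow(as.data.table(correlations))) {
    r <- as.data.table(correlations)$rho
    correlation <- list(
      n = length(r), mean = mean(r), median = median(r),
      n_above = sum(r > rho_cutoff), n_below = sum(r < -rho_cutoff),
      n_weak = sum(abs(r) <= rho_cutoff), rho_cutoff = rho_cutoff
    )
  }
  structure(list(
    n_union = agr$n_union,
    per_method_counts = agr$per_method,
    agreement_histogram = agr$histogram,
    n_reliable = nrow(rel_j),
    per_sample = per_sample_counts(ev, reliable),
    category_counts = category_counts,
    n_genes_with_circ = n_genes,
    circ_per_gene_distribution = dist,
    correlation = correlation,
    methods_enabled = methods_enabled
  ), class = "summary_stats")
}

html_table <- function(dt) {
  dt <- as.data.table(dt)
  hdr <- paste0("<tr>", paste0("<th>", names(dt), "</th>", collapse = ""), "</tr>")
  rows <- if (nrow(dt)) apply(dt, 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")) else character()
  paste0("<table>\n", hdr, "\n", paste(rows, collapse = "\n"), "\n</table>")
}

#' Render summary statistics as TSV tables and one HTML page
#'
#' Writes `stats/*.tsv` (the numeric test surface) and, unless
#' `html = FALSE`, a deterministic `summary.html` with four sections: run
#' summary, detection and method agreement, reliable-set analyses, software
#' versions.
#'
#' @param stats a `summary_stats` object.
#' @param out_dir output directory (created if needed).
#' @param html write the HTML page too (default TRUE).
#' @param plots also emit PNG bar charts of the detection/agreement tables
#'   (requires ggplot2; the TSVs remain the numeric source of record).
#' @param versions named character vector of software versions to report;
#'   default: R and this package.
#' @return `out_dir`, invisibly.
#' @export
render_summary <- function(stats, out_dir, html = TRUE, plots = FALSE,
                           versions = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  statdir <- file.path(out_dir, "stats")
  dir.create(statdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(statdir)) stop("cannot create ", statdir, call. = FALSE)
  if (is.null(versions))
    versions <- c(R = paste(R.version$major, R.version$minor, sep = "."),
                  circonsensus = as.character(packageVersion("circonsensus")))

  per_method <- data.table(
    method = names(stats$per_method_counts),
    n_circrnas = as.integer(stats$per_method_counts),
    pct_of_union = if (stats$n_union > 0)
      pct(as.integer(stats$per_method_counts), stats$n_union, 0L) else 0
  )
  overview <- data.table(
    statistic = c("n_union", "n_reliable", "pct_reliable", "n_genes_with_circ"),
    value = c(stats$n_union, stats$n_reliable,
              if (stats$n_union > 0) pct(stats$n_reliable, stats$n_union, 1L) else 0,
              stats$n_genes_with_circ)
  )
  categories <- data.table(
    category = names(stats$category_counts),
    n_circrnas = as.integer(stats$category_counts),
    pct_of_reliable = if (stats$n_reliable > 0)
      pct(as.integer(stats$category_counts), stats$n_reliable, 1L) else numeric(0)
  )
  corr <- stats$correlation
  correlation <- data.table(
    statistic = c("n_computable", "mean_rho", "median_rho",
                  paste0("n_above_", corr$rho_cutoff),
                  paste0("n_below_minus_", corr$rho_cutoff), "n_weak"),
    value = c(corr$n, corr$mean, corr$median, corr$n_above, corr$n_below,
              corr$n_weak)
  )
  tables <- list(
    overview = overview, per_method = per_method,
    agreement_histogram = stats$agreement_histogram,
    per_sample = stats$per_sample, categories = categories,
    circrnas_per_gene = stats$circ_per_gene_distribution,
    correlation = correlation,
    versions = data.table(software = names(versions), version = unname(versions))
  )
  for (nm in names(tables))
    fwrite(tables[[nm]], file.path(statdir, paste0(nm, ".tsv")), sep = "\t")

  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot(per_method,
            ggplot2::aes(x = method, y = n_circrnas)) +
      ggplot2::geom_col() +
      ggplot2::labs(y = "circRNAs detected", x = NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(statdir, "per_method.png"), gg,
                    width = 5, height = 3.5, dpi = 120)
    if (nrow(stats$agreement_histogram)) {
      gh <- ggplot2::ggplot(stats$agreement_histogram,
              ggplot2::aes(x = factor(n_methods), y = n_circrnas)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "methods in agreement", y = "circRNAs") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(statdir, "agreement_histogram.png"), gh,
                      width = 5, height = 3.5, dpi = 120)
    }
  }

  if (html) {
    page <- c(
      "<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
      "<title>circRNA consensus run summary</title></head><body>",
      "<h1>circRNA consensus run summary</h1>",
      "<h2>1. Run summary</h2>",
      sprintf("<p>Samples: %d. Methods: %s.</p>",
              nrow(stats$per_sample),
              paste(stats$methods_enabled, collapse = ", ")),
      html_table(overview),
      "<h2>2. Detection and method agreement</h2>",
      html_table(per_method), html_table(stats$agreement_histogram),
      html_table(stats$per_sample),
      "<h2>3. Reliable-set analyses</h2>",
      html_table(categories), html_table(stats$circ_per_gene_distribution),
      html_table(correlation),
      "<h2>4. Software versions</h2>",
      html_table(tables$versions),
      "</body></html>"
    )
    writeLines(page, file.path(out_dir, "summary.html"))
  }
  invisible(out_dir)
}
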