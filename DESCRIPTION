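Package: circonsensus
Title: Multi-Method Consensus Detection, Annotation and Quantification of
    Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes back-splice junction calls produced by four circular
    RNA detection tools (CIRCexplorer, CIRI, find_circ and testrealign) into a
    single coordinate space, selects a reliable circRNA set by requiring
    joint detection by multiple methods with minimum back-splice read support,
    annotates junctions against gene models as exonic, intronic or intergenic,
    quantifies circRNA expression in reads per million mapped (RPM), computes
    log2 fold changes and cumulative-expression summaries, and correlates
    circRNA with host-gene expression. Includes a synthetic detector-output
    generator that plants a ground-truth circRNA set over a toy annotation for
    end-to-end validation, and a report module producing the aggregate
    statistics of a run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
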