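---
title: "Methods: multi-detector circRNA consensus, annotation and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-detector circRNA consensus, annotation and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

Back-splice detection tools are run upstream, outside this package; their
native per-sample output files are the input. `circonsensus` models one unit
of evidence as a *back-splice call*: one junction, reported by one method,
in one sample, with a count of junction-spanning reads. Everything else is
derived from the multiset of calls:

1. calls are converted to a shared coordinate convention and merged into
   *circRNAs* keyed by exact back-splice position;
2. a *reliable* subset is selected by joint method detection and read
   support;
3. the reliable set is annotated against gene models and quantified in RPM;
4. circRNA expression is correlated with host-gene expression;
5. aggregate statistics are reported.

## Coordinate conventions

The internal convention is 0-based half-open (BED-like), chosen so that
every dialect has exactly one conversion site, defined by per-method
`(start_offset, end_offset)` pairs in `default_dialects()`. CIRI-style
1-based inclusive coordinates map with offsets (−1, 0); the BED-derived
dialects are identity. The offsets are configuration, not code: if a
particular testrealign build shifts its coordinates relative to the other
tools, the correction belongs in the dialect spec. Display IDs
(`"11:33286413-33287511:+"`) use 1-based inclusive coordinates, the
convention of circRNA databases; the chromosome string is passed through
untouched, so a `chr` prefix appears iff the annotation used one.

## Junction identity and strand

Cross-method matching is **exact** on `(chrom, start, end)`. A tolerance
window was deliberately rejected: back-splice positions *are* the identity
of a circRNA, and a ±n-bp match rule would silently merge distinct circular
isoforms of the same gene, which frequently share one boundary. Systematic
per-tool shifts are handled in the dialect offsets, where they can be
audited.

The junction key is strandless. Detectors occasionally disagree on strand,
and a stranded key would count the same junction twice. The reported strand
is the majority vote over evidence rows; ties and all-unknown evidence give
`"."`.

## The reliable-set rule

A circRNA is reliable when at least `min_methods` (default 2) distinct
enabled methods detect it and its read support reaches `min_reads`
(default 2). Two points were genuinely open and are resolved as follows:

* **Support statistic.** "At least two back-splice reads" could mean per
  method, per sample, or summed. The default is the *maximum* over
  (sample, method) evidence entries: the four methods re-estimate the same
  molecules from the same library, so summing across methods would inflate
  support with correlated evidence. `sum_over_methods` and
  `sum_over_samples` are available for sensitivity analysis.
* **Scope.** Method agreement is pooled across samples by default, matching
  the dataset-wide view in which a junction seen by CIRI in sample 1 and by
  find_circ in sample 2 counts as jointly detected; `per_sample` scope
  requires agreement within at least one single sample.

Both conditions are evaluated conjunctively on the same input set. The rule
is monotone in both thresholds (raising either never enlarges the set) and
`min_methods = min_reads = 1` is the identity; both properties are enforced
by tests over hundreds of randomized evidence tables.

## Annotation categories

Each junction end is a single boundary base: the start-side base is the
internal start, the end-side base is internal end − 1. An end is *exonic*
if inside ≥1 annotated exon, *intronic* if inside ≥1 gene span but no exon,
*intergenic* otherwise. Per-junction labels combine the ends: both exonic →
`exonic`; both intra-gene but not both exonic → `intronic`; both outside →
`intergenic`; mixed classes are joined with `|` in the order
exonic, intronic, intergenic. When a gene lies strictly inside the junction
span without containing either end, the part `intergenic spanning gene` is
appended and the spanned genes join the gene list — this reproduces the
composite vocabulary (`exonic|intergenic spanning gene`) used for circRNAs
that swallow small genes (snRNA pseudogenes and similar) whole.

Overlap ignores strand: circRNAs are routinely annotated to genes on either
strand, including antisense pseudogenes. Exon matching is containment, not
splice-site equality — the classification is about where the ends *fall*,
not whether they reuse annotated splice sites. Stranded or exact-boundary
variants can be composed from `classify_end()`, which exposes the per-end
layer directly; they are not separate modes of `categorize_circrna()`.

## Expression and correlation

RPM = count × 10⁶ / total mapped reads, with the per-sample count reduced
across methods by the same `max` rule as the consensus support (sum and
mean selectable). Log₂ fold changes are computed without replicates as
log₂((a + c)/(b + c)) with pseudocount c = 1 RPM: zeros are common in
back-splice counts (a junction strongly expressed in macrophages may have 0
reads in monocytes), so an additive pseudocount keeps every fold change
defined while shrinking those of barely-expressed circRNAs toward 0. The
value 1 RPM is a default flag, not a constant.

A (circRNA, gene) correlation is *computable* when the pair shares at least
3 samples and neither expression vector is constant; Spearman's ρ uses
average ranks for ties (`stats::cor`, cross-checked in tests against a
hand-computed Pearson-on-average-ranks oracle). Non-computable pairs are
counted, not silently dropped. No p-values or multiple-testing correction
are attached: with four samples the correlations are descriptive screening
values, and presenting them as tested hypotheses would overstate them.

## Report arithmetic

Percentages are always recomputed from the printed integers by `pct()`,
which rounds **half-up** (17.50% → 18%), the convention that reproduces the
published summary arithmetic of this analysis style; R's default
round-half-even would print 17.5 → 18 but 16.5 → 16. A small epsilon
(10⁻⁹) keeps values that land on .5 after binary round-off on the upward
side. Rendered TSVs are the numeric test surface; the HTML page is
assembled deterministically from the same tables.

## The synthetic-data generator

`generate_fixture()` emulates the *output* of a multi-detector study, not
reads or alignments. Its defaults define the study conditions used
throughout the tests:

* 4 samples, mirroring the monocyte/macrophage two-genotype design;
* genes laid end-to-end over four chromosomes with 2–5 exons of 100–300 bp,
  introns of 200–500 bp and intergenic gaps of 5–10 kb — wide enough that
  planted exonic, intronic and intergenic circRNAs are unambiguous;
* per-(circRNA, sample) read counts from a negative binomial with mean 5
  and size 2, giving the zero-inflation seen in real back-splice counts;
  one sample per junction is bumped to ≥2 reads so that every planted
  circRNA is expressed at the reliable-set read threshold — the recovery
  experiments probe method-consensus behaviour, not read-depth dropout;
* category mix 0.90/0.05/0.05 exonic/intronic/intergenic: strongly
  exonic-skewed, as in real data where ~98% of reliable circRNAs are
  exonic, but with enough intronic/intergenic mass to exercise those paths
  at n = 500;
* per-method detection is an independent Bernoulli per (circRNA, method),
  which makes the two-method agreement rate analytically available —
  P(≥2 of 4) by enumeration — and testable within binomial 3σ bounds;
* false positives are method-private by construction (drawn in per-method
  reserved coordinate zones beyond the annotated chromosomes), encoding the
  structural claim that combining methods removes loose predictions; every
  detecting method reports the same true count, so truth → writers →
  parsers → harmonization conserves read counts exactly.

What the generator does **not** emulate: correlated errors between methods
(two tools fooled by the same genomic feature), coordinate jitter around
the true breakpoint, method-specific count biases, and linear/circular
expression coupling. Passing recovery tests therefore shows the pipeline's
bookkeeping and set logic are exact under the stated error model, not that
two-method agreement has any particular false-discovery rate on real data
(where detector errors are demonstrably not independent).

## Problem sizes and numerical choices

Tests run fixtures of 25–500 planted circRNAs over 30–250 genes, sizes at
which every oracle (linear scans, exhaustive enumerations, brute-force set
logic) is exact and fast; the acceptance script uses 500 circRNAs per
scenario. Degenerate inputs are defined, not accidental: empty detector
files parse to empty tables; an empty evidence table flows through
selection, annotation and reporting as all-zero statistics; all-zero
expression columns are an error for cumulative-share (the quantity is
undefined); `testrealign` linear events (`N` rows) are skipped as
non-back-splices rather than rejected. Malformed lines are errors naming
the line number — silent coercion would corrupt consensus counts — with an
explicit `lenient` mode that downgrades them to warnings.

## Limitations

* The reliable-set rule treats methods symmetrically; there is no
  per-method weighting or probabilistic reconciliation.
* Internal circRNA structure (which exons the circle contains) is not
  inferred; the junction alone cannot distinguish exonic circRNAs from
  exon–intron circles.
* Config-driven runs execute stages sequentially; outputs are contractually
  identical to any concurrent schedule since stages communicate only
  through their inputs, but no scheduler is included.
* The correlation module reports descriptive ρ only; differential
  expression with replicates is out of scope by design.
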