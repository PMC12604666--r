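---
title: "Methods: variant matching, symptom-weighted prediction and gene profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant matching, symptom-weighted prediction and gene profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgdtools)
```

`rgdtools` implements three computations used when screening population
cohort genomes against rare-genetic-disorder (RGD) knowledge: matching
cohort variants to a pathogenic-variant catalog, ranking candidate
disorders from selected clinical symptoms, and profiling pathogenic
variant density along a gene. This vignette records the models, their
assumptions, the tunable parameters, and the design choices that were
genuinely open.

## Variant matching

### Model

A cohort variant *v* = (chrom, pos, ref, alt) is compared with a catalog
*C* of ClinVar-like records. Classification is a strict two-level rule:

* **IDENTICAL** — some catalog entry matches (chrom, pos, ref, alt)
  exactly;
* **SIMILAR** — otherwise, some entry shares (chrom, pos) but differs in
  the allele pair;
* **UNMATCHED** — no entry shares the site.

Identity takes precedence over similarity when both hold for different
entries at one site. "Similar" is interpreted at the *allele* level (same
site, different ref/alt strings), not via VCF genotype (GT) fields: the
canonical similar example contrasts a `C>T` substitution with an `AC>A`
deletion at the same coordinate, which is an allele-representation
difference, and sites-only cohort releases carry no sample columns to
compare genotypes with.

Coordinates are treated as GRCh38 by convention; no liftover is
performed. Chromosome labels are canonicalized (`13` → `chr13`,
`MT` → `chrM`) so VCF and catalog dialects join.

### Representation normalization is opt-in

By default no trimming or left-alignment is applied: normalizing would
silently reclassify pairs that differ only in padding, changing the
identical/similar partition the strict rule defines. For users who want
representation-robust matching, `match_cohort(..., normalize = TRUE)`
trims the shared suffix then the shared prefix of each ref/alt pair
(keeping at least one base, advancing the position over trimmed prefix
bases). Full left-alignment is deliberately not attempted: it requires
the reference genome sequence, which the plain-text catalogs this package
operates on do not carry, so the normalization offered is exactly the
part that is well-defined without a FASTA.

### Annotation and aggregation

Matched variants inherit the catalog's annotations. Clinical-significance
strings are mapped deterministically onto five categories; `PATHOGENIC`,
`LIKELY_PATHOGENIC` and `PATHOGENIC_CONFLICTING` (conflicting
interpretations of pathogenicity) together constitute the "pathogenic"
stratum, the severity order for picking a best-matched entry being
pathogenic > likely pathogenic > conflicting > benign > other, with
identical-matching entries preferred over site-only matches. Condition
strings carry inheritance as a trailing token — `(AD)`, `(AR)`, `(XL)` —
and compound strings are split on `" and "` only when *every* fragment
carries its own token, so names legitimately containing "and"
("Microcephaly, normal intelligence and immunodeficiency") survive. A
variant whose matched conditions mix two or more distinct known modes is
summarized as `MULTI`. The `(XL)` token is accepted although published
tables rarely print one; X-linked variants are part of the annotation
vocabulary and need a token form.

Published per-inheritance tables sometimes omit the per-row token because
the table's title carries it (a recessive-disorder table with one
tokenless row). `read_variant_catalog(..., default_mode =)` supplies that
table-level context to tokenless conditions; the verbatim condition
string is retained either way.

Summaries count **distinct sites** (chrom, pos), not variant records:
published totals are phrased as "mutation sites", and multi-allelic
cohort records would otherwise inflate counts. Per-variant records remain
available, and deduplication happens after classification. On every
input the summary satisfies
`mapped = identical + similar` and
`pathogenic = pathogenic_identical + pathogenic_similar`.

## Symptom-weighted disorder prediction

Each disorder–symptom association carries an ordinal frequency term. The
default weight table is

| term | weight |
|---|---|
| always | 4 |
| very frequently | 3 |
| frequently | 2 |
| sometimes | 1 |
| unusually | 0.5 |
| rarely | 0.5 |
| (none) | 0 |

The published description maps the three weakest informative terms to the
two weights "1 and 0.5" without saying which gets which; this package
fixes *sometimes* → 1 and *unusually*/*rarely* → 0.5 because that is the
only assignment preserving the monotone ordering of the listed
vocabulary. The table is an argument everywhere, so the alternative
reading is a one-line change; any supplied table must be non-negative and
monotone non-increasing.

A disorder's score is the raw sum of weights over the selected symptoms
it is associated with — no normalization by the disorder's total symptom
count, since the procedure is defined purely as a summation. Zero-score
disorders are dropped (a disorder sharing no selected symptom is not a
prediction), the rest are sorted by score descending with exact ties
broken alphabetically by name (case-insensitive, giving a deterministic
order since names are unique keys), and the list is truncated at *k* = 10
by default. Unrecognized frequency text degrades to weight 0 with a
warning rather than erroring, because source vocabularies are not closed.

## Gene segment profiles and tracks

A gene span [start, end] (1-based, inclusive) is tiled into consecutive
windows of `width` = 500 bp by default, anchored at the gene start in
genomic coordinates regardless of strand; the last window is truncated at
the gene end, so the windows partition the span exactly. Intervals are
closed, and a variant at a window's last base belongs to that window;
consequently total counts are conserved for any width, which the tests
assert directly. `strand_relative = TRUE` renumbers windows 5′→3′ for
display on minus-strand genes without moving coordinates. By default the
profile counts the three pathogenic categories; the category set is an
argument because published segment tables do not state whether
likely-pathogenic and conflicting variants are included.

The four-tier track model (chromosome context, gene span, exon
intervals, variant positions) is a deterministic tibble; `autoplot()`
renders it. BED export converts to 0-based half-open coordinates only at
the file boundary, writes the per-segment count into the score column,
and round-trips through `read_bed()`.

## Synthetic data

The generators emulate the *structure* of a cohort-versus-catalog study:
catalogs with unique sites, controlled significance/inheritance
composition (multinomial draws whose realized counts are recorded as
truth), cohort VCFs with exactly planted identical / similar / unmatched
counts, symptom catalogs with an exhaustively scored scripted selection,
and exon-bearing gene models. Planting is constructive: identical cohort
variants are verbatim catalog copies; similar ones sit at catalog sites
with an alternate allele chosen to clash with no catalog allele pair at
that site; unmatched ones occupy a disjoint position range. A single
integer seed drives everything, each generator runs in its own RNG scope
(regenerating one file never perturbs another, and the caller's RNG
stream is untouched), and output is byte-identical across runs.

What the fixtures do **not** imitate: real allele-frequency spectra,
linkage structure, mutational signatures, indel-representation ambiguity
beyond simple padding, or real catalog content. Passing tests therefore
demonstrate correctness of the classification, scoring and counting
logic under the stated conventions — not concordance with any external
release, which additionally depends on the catalog snapshot and cohort
version used.

Default study conditions follow the published analysis scale where one
is stated: the full-scale check plants 8645 mapped sites of which 4826
are identical and 3819 similar, with 432 and 699 pathogenic respectively;
the small fixture set defaults to a 100-entry catalog with planted
(5, 3, 2) classes. Property suites run on deliberately small instances
(catalogs ≤ 80 entries, cohorts ≤ 1000 variants, ≤ 50 disorders,
100-seed sweeps) — sizes at which the brute-force oracles
(double-loop classifier, direct-summation scorer, per-position window
membership) are exact and fast.

## Numerical and degenerate-input choices

* Positions are 32-bit integers; widths and k must be ≥ 1.
* Empty catalogs classify everything UNMATCHED; empty cohorts yield
  empty, well-typed results; a gene of length 1 yields one length-1
  segment.
* Rows failing structural checks (non-integer position, non-ACGTN
  alleles, malformed exon intervals) are rejected with a warning naming
  the count, never silently dropped or repaired; symbolic/breakend VCF
  alleles are skipped and counted.
* Interchange files are UTF-8, tab-delimited, `.` for missing; writers
  and readers are inverse on every valid in-memory value (property-tested
  round trips).
* Published tables are bundled verbatim, including internally
  inconsistent rows whose two printed coordinate columns disagree; both
  versions are recorded (`pos` from the catalog column, the other
  verbatim in `indigen_id`) and never silently reconciled.

## Limitations

* Matching is representation-sensitive by design; cross-representation
  recall requires the opt-in trimming, and true left-alignment would
  need a reference FASTA.
* Prediction does no ontology expansion (a selected symptom matches only
  its literal term) and no probabilistic calibration.
* Allele frequencies are out of scope: sites-only cohort VCFs carry no
  genotype or sample information.
* Headline counts from any real cohort depend on the external cohort
  release and catalog snapshot; this package reproduces the aggregation
  identities and worked examples, not the raw-data extraction.
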