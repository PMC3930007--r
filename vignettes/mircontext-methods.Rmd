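---
title: "Methods: genomic context and co-expression analysis of miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic context and co-expression analysis of miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircontext)
```

`mircontext` analyses how the genomic context of miRNA genes — their
location relative to protein-coding genes, their organization in
clusters, and the conservation of their seed regions — relates to their
expression in bulk tissue profiles. This vignette documents the models
and conventions the package commits to, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reading was defensible.

## Coordinates and input formats

All annotation enters as GFF3 (miRBase dialect, with precursor and
mature records linked by `Derives_from`) or GTF/GFF3 gene models, parsed
by `rtracklayer`. Internally every interval is **0-based half-open**
(BED-style): a GFF record printed as 1-based inclusive `[s, e]` becomes
`[s−1, e)`, so widths are always `end − start` and conversion back to
GFF is `start + 1`. One stated convention avoids off-by-one drift across
modules; the reader validates each non-comment line (9 tab fields,
sane coordinates) so malformed input fails with a line number.

Mature miRNAs with the same name at several loci (miR-378 is the
canonical bovine example, coded on chromosomes 4 and 7) are merged into
one mature entry carrying all coding gene ids; the mature/precursor
relationship is many-to-many throughout. Records may appear in any
order; parent resolution is two-pass. A missing strand is rejected for
miRNA and gene features because the cluster rule is strand-aware.

## Location classes

Each precursor is classified against all transcripts of all gene models
with precedence **mirtron > exonic > intronic > intergenic**:

* *mirtron* — the precursor spans an intron end to end. The boundary
  tolerance defaults to 0 nt (the definition is "the entire length of an
  intron") but is configurable (`mirtron_tolerance`) because annotation
  boundary jitter of a few nucleotides is common in practice.
* *exonic* — at least 1 bp of exon overlap, in any transcript. A
  precursor inside an intron of one transcript but overlapping an exon
  of another is exonic: precedence applies across transcripts.
* *intronic* — fully contained in an intron with no exon overlap. All
  qualifying host genes are listed (a precursor can sit in introns of
  two overlapping genes), and host strand is recorded as
  sense/antisense rather than used as a filter — intronic miRNAs are not
  required to lie on the host's sense strand.
* *intergenic* — none of the above. A precursor on a chromosome absent
  from the gene models is classified intergenic with an
  `unknown_chromosome` flag and a warning rather than an error, so one
  scaffold mismatch does not kill a run.

## Cluster rule

Clustered miRNA genes are those with inter-miRNA distance **< 10 kb on
the same strand**. Two decisions were open:

* *Gap metric.* "Inter-miRNA distance" does not state its endpoints; the
  package uses the conservative end-to-start gap between precursor
  intervals (`next.start − prev.end`), configurable via `max_gap`.
  Overlapping precursors (negative gap) cluster. The bound is strict:
  a gap of exactly 10,000 bp does not cluster.
* *Chaining.* Membership is single-linkage over consecutive genes sorted
  by start, which equals the transitive closure of the pairwise relation
  (tested against a brute-force union-find oracle on random fixtures up
  to 200 genes). This matches how multi-member clusters such as the
  17~92 cluster are described as one unit even though their extreme
  members are farther than 10 kb apart.

A mature miRNA is *clustered* when any of its coding loci is clustered,
and its location classes are the set over loci — so a mature like
miR-378 reports `{intronic, intergenic}`.

## Normalization, detection, and the core set

Raw intensities are normalized per sample to the 75th percentile:
`v → log2(v) − P75(log2 v of the sample) + offset`. Percentiles use
linear interpolation between order statistics (R's quantile type 7);
the exact convention used by commercial array software is not public,
so the choice is stated here and recorded in the matrix attributes.
Non-positive raw values cannot be logged and are masked `NA` —
the convention the generator also uses for undetected probe cells.
A sample with no positive values is an error naming the sample.

Detection is either an explicit flag matrix (when scanner presence
calls are available) or `value > floor` on the normalized scale, with
the matrix minimum as the default floor (the lowest observed value is
treated as the undetected baseline).

The core rule — "expressed in all individuals in at least one time
point" — admits two readings, both implemented:

* **per-individual** (default): each individual has ≥ 1 of its own
  samples detected; time points may differ between individuals. This is
  the reading in which "at least one time point" attaches to each
  individual.
* **common-timepoint**: one time point exists at which all individuals
  detect the miRNA simultaneously.

## Summary statistics and the power law

Per-miRNA mean, sample SD (n−1) and CV are computed across all samples.
Because percentile normalization centres log intensities so that ~75% of
values per sample are negative, means on the log scale are mostly
non-positive and a CV would be meaningless there. Summaries are
therefore taken by default on the **back-transformed linear scale**
(`2^normalized`, i.e. intensity relative to the pinned percentile),
which keeps means positive and makes CV the conventional relative
variability; `scale = "log"` is available and the choice is explicit in
the API. Rows with non-positive mean are flagged and excluded from the
power fit.

The mean–CV relation `mean = a · CV^b` is fitted by ordinary least
squares of `log(mean)` on `log(CV)` (points with positive mean and CV
only; ≥ 3 points required); `a` is the back-transformed intercept, `r²`
is taken on the log–log scale, and the Pearson correlation of mean and
CV on the untransformed scale is reported alongside. The fit is
scale-equivariant: rescaling all means by `c` multiplies `a` by `c` and
leaves `b` and `r²` unchanged — which matters because percentile
normalization fixes the intensity scale only up to the percentile
anchor.

Category comparisons follow the era's standard toolkit: a pooled-variance
two-tailed t-test for two groups (Welch by flag), one-way ANOVA plus
Tukey's HSD at α = 0.05 for three or more. No multiple-testing
correction is applied by default; Benjamini–Hochberg is available where
p-value lists are produced (enrichment).

## Relevance networks

Pearson correlations are computed between core-miRNA rows over all
samples (pairwise-complete; zero-variance rows are excluded with a
warning). An edge is kept when `R² ≥ r2_threshold` — inclusive, with
0.95 as default — and the sign of R is retained, so strongly
anti-correlated pairs are connected too. "Networks" are the connected
components of size ≥ 2, not cliques: co-expression groups chain through
shared members. Components are reported largest-first. Raising the
threshold can only shrink the edge set and the components (tested as a
monotonicity property).

## Seeds, conservation, and predicted targets

The seed is the **first 7 nt of the mature sequence** by default. The
common database convention is positions 2–8; the window is configurable
(`window_start`, `window_len`) and the default follows the 5′-end
definition used in the modelled study. Matures with identical seeds are
collapsed into one analysis entry named by the slash-joined sorted
member list (the UGGGGCU trio miR-1584/2412/2374 is the motivating
case).

Conservation classes (highly conserved / conserved / poorly conserved)
are **database labels copied from a user-supplied TargetScan-style
family table**, not computed from alignments. A seed is species-specific
when the table lists it under no species besides the focal one; since
specificity is relative to whatever table snapshot is supplied, the
output flags seeds absent from the table (`in_table = FALSE`) so such
calls can be audited. Species specificity is only asserted for poorly
conserved seeds, keeping the output self-consistent even for
inconsistent tables.

Target predictions are filtered at total context+ score ≤ −0.3
(inclusive; more negative = stronger predicted repression) and counted
as **unique target genes** per entry, so multiple sites in one gene
count once.

## qPCR processing

Technical replicates are averaged per (sample, assay); replicate SD
above `sd_limit` (default 0.5 cycles) flags the reaction, and missing
reactions go to a gap report instead of an exception. ΔCt is
`Ct_target − Ct_reference` and the ΔΔCt fold change is `2^−ΔΔCt`.

For host-gene/intronic-miRNA correlation, per-sample expression is
taken as **−ΔCt** (lower Ct = higher expression, so positive R means
co-expression); genes are referenced against beta-actin and miRNAs
against miR-181a by default, both configurable. The two-tailed p-value
comes from `t = R·√(n−2)/√(1−R²)` with n−2 df — the same transform lets
printed correlation tables be re-checked from R and n alone, e.g.
`pearson_pvalue(0.624, 12)` = `r round(pearson_pvalue(0.624, 12), 3)`.
The t-approximation agrees with a permutation p-value within Monte-Carlo
error at n = 12 (tested).

## Enrichment

`fisher_right(k, n, m, N)` is the right-tailed Fisher exact test: the
hypergeometric tail `P(X ≥ k)` for `k` of `n` query genes falling in a
set of `m` within a universe of `N`. The universe must be explicit —
there is no defensible default universe, and the choice changes p-values
substantially — and all four counts are reported per term so any
universe convention can be audited. Symbol matching is case-insensitive
and exact; alias resolution is out of scope and a known limitation.

## The synthetic-data generator

`sim_config()` fixes the study conditions; all randomness flows from its
mandatory seed (outputs are byte-identical across runs). Defaults
emulate the modelled design:

| parameter | default | emulates |
|---|---|---|
| individuals × time points | 8 × 3 | 24 arrays |
| detected / core miRNAs | 224 / 155 | detection census |
| location mix | 95 / 57 / 2 / 1 | intergenic / intronic / exonic / mirtron per-gene tally |
| cluster sizes | 6, 3, 3, 2, 2, 2 | representative cluster census, gaps 2–8 kb |
| co-expression blocks | 14, 12, 2, 2, 2, 2 | the six observed networks |
| within-block R | 0.99 | "highly correlated" pairs |
| power law | a = 0.5967, b = −0.999, σ = 0.2 | mean–CV trend with scatter |
| CV range | 0.05–1.9 | observed CV extremes |
| qPCR couplings | R = 0.624, 0.193, 0.635, 0.001 at n = 12 | host/miRNA pairs |

Annotation geometry realizes each class exactly (mirtrons coincide with
an intron, exonic precursors straddle an exon boundary, intronic ones
sit strictly inside introns, intergenic ones lie > 10 kb from
everything unless planted in a cluster), so the classifier and cluster
detector are expected to recover 100% of planted labels — and do, which
is what the planted-truth tests assert. Two multi-locus matures are
planted: one combining an intronic with an intergenic locus and one
present in two clusters.

Expression values are log-normal per miRNA with exactly the planted
(mean, CV) on the linear scale; block members share a per-sample latent
factor with the noise ratio set analytically (`√ρ·z + √(1−ρ)·ε`) rather
than via covariance factorization, keeping the construction auditable.
Undetected cells are written as 0 intensity. Two properties of real
data are deliberately **not** emulated: probe-specific effects such as
GC bias on hybridization intensity, and any diet or time-point effect —
the groups are labels only. Passing tests therefore show that the
algorithms recover planted structure under the stated statistical
model, not that the model captures every property of real arrays.

Two sampling caveats, measured and documented rather than hidden: the
observed within-block correlation over 24 samples is slightly attenuated
relative to the latent coupling (median ≈ 0.988 at 0.99) because the
per-sample 75th percentile is itself estimated from ~224 values; and a
size-2 block's single edge can miss `R² ≥ 0.95` for an unlucky seed, so
exact six-network recovery holds for most but not all seeds. Fixed-seed
tests make these checks deterministic.

## Problem sizes and runtime choices

Tests and the acceptance script run at the study's own scale — 155–224
miRNAs × 24 samples, 12 qPCR samples, cluster fixtures up to 200 genes,
Fisher fixtures up to N = 200, 150-point power fits, and 10,000-fold
permutation checks — sizes at which every check completes in seconds
while still exercising the statistics at realistic n.

## Known limitations

* Conservation is only as good as the supplied family table; no
  alignment is performed.
* Detection without scanner flags reduces to a threshold convention.
* The exact percentile and flooring behaviour of commercial array
  software is unknown; reproductions of published normalized values can
  only be approximate.
* Gene symbols are matched exactly (case-insensitive); no alias
  resolution.
* No batch correction and no differential-expression machinery — the
  package characterizes a tissue's core expression, not contrasts.
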