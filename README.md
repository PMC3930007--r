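# mircontext

`mircontext` relates the **genomic context of microRNA (miRNA) genes** to
their **expression and function** in bulk tissue profiles. It was built
around a bovine subcutaneous adipose-tissue study design — eight steers
biopsied at three time points (24 arrays) — but every step takes ordinary
annotation and expression files, so it applies to any comparable design.

The package is aimed at researchers asking questions such as: which miRNAs
form the *core* expression set of a tissue (detected in every individual)?
Are miRNA genes located in introns, exons, between genes, or are they
mirtrons? Which miRNA genes sit in genomic clusters and are presumably
co-transcribed? Do co-expressed miRNAs form relevance networks, and do
intronic miRNAs track their host genes?

## What it computes

* **Genomic context** — each miRNA precursor is classified against
  protein-coding gene models with precedence
  *mirtron > exonic > intronic > intergenic*: a mirtron spans an entire
  intron; exonic overlaps an exon by ≥ 1 bp; intronic lies fully inside an
  intron. Clusters are maximal same-strand chains with consecutive
  inter-precursor distance **< 10 kb** (single linkage, strict bound).
* **Core expression set** — intensities are percentile-normalized per
  sample (`log2(v) − P75(log2 v)`, type-7 quantile); a miRNA is *core*
  when every individual detects it in at least one time point.
* **Mean–CV power law** — per-miRNA mean and coefficient of variation
  (CV = sd/mean) are related by `mean = a · CV^b`, fitted by OLS on the
  log–log scale; the Pearson R of mean vs CV is reported alongside.
* **Relevance networks** — edges connect miRNA pairs with
  `R² ≥ 0.95` (Pearson, over all samples, sign retained); networks are
  the connected components of size ≥ 2.
* **Seeds and conservation** — 7-nt 5′ seed regions, seed-sharing groups,
  conservation classes from a TargetScan-style family table,
  species-specific seeds, and target-prediction filtering at total
  context+ score ≤ −0.3 with unique-gene counts.
* **qPCR** — technical-replicate aggregation, ΔCt against reference
  assays, ΔΔCt fold change (`2^−ΔΔCt`), and host-gene vs intronic-miRNA
  Pearson correlation with the two-tailed t-transform p-value
  (`t = R·√(n−2)/√(1−R²)`).
* **Enrichment** — right-tailed Fisher's exact test
  (`p = P(X ≥ k)`, hypergeometric) of a query gene list against GMT gene
  sets over an explicit universe.
* **Synthetic data** — a seeded generator emits annotation (GFF3 + GTF),
  expression (TSV + sample sheet) and qPCR Ct tables with known ground
  truth: planted location classes, clusters, co-expression blocks, a
  planted power law and planted host/miRNA couplings.

## Worked example

The synthetic generator reproduces the modelled study design end to end:

```r
library(mircontext)
cfg <- sim_config(seed = 42)

anno   <- simulate_annotation(cfg)
prec   <- read_mirna_gff(anno$mirna_gff)
models <- read_gene_models(anno$gene_gtf, "gtf")
ctx    <- annotate_context(prec$genes, models)
table(ctx$location_class)
#>     exonic intergenic   intronic    mirtron
#>          2         95         57          1

expr <- simulate_expression(cfg)
d    <- read_expression(expr$matrix_tsv, expr$sample_sheet_tsv)
nm   <- normalize_percentile(d$matrix)
core <- detect_core(nm, d$samples)
length(core$core)
#> 155 of 224 miRNAs form the tissue core set

fit_power(summarize_expression(nm[core$core, ]))
#> Power fit: y = 0.1393 * x^-1.0791  (R2 = 0.884, n = 155)
#> Pearson R (mean vs CV, untransformed): -0.626

build_network(correlation_matrix(nm[core$core, ]), r2_threshold = 0.95)
#> Relevance network (R2 >= 0.95): 155 nodes, 147 edges, 6 component(s)
#>   network 1 (n = 14): syn-miR-001, ..., syn-miR-014
#>   network 2 (n = 12): syn-miR-015, ..., syn-miR-026
#>   network 3 (n = 2): syn-miR-027, syn-miR-028
#>   ...
```

The context table says where each precursor lies (95 intergenic, 57
intronic, 2 exonic, 1 mirtron — the planted mix); 155 of 224 miRNAs pass
the per-individual core rule; the power fit recovers the planted
negative exponent relating expression level to variability (highly
expressed miRNAs vary least); and the six recovered networks match the
planted co-expression blocks (sizes 14, 12, 2, 2, 2, 2).

The package also ships curated reference tables under `inst/extdata/`
(the 23 bovine-specific adipose core miRNAs with their seeds and
expression, and the core-set conservation/location tallies) used by the
reproduction script below.

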