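# one gene, three exons at (0-based) [1000,1200) [1500,1800) [2600,3000)
std_models <- function(strand = "+") {
  genes <- data.frame(gene_id = "G1", name = "HOST1", chrom = "chr1",
                      start = 1000L, end = 3000L, strand = strand,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "G1", transcript_id = "T1", chrom = "chr1",
                      start = c(1000L, 1500L, 2600L),
                      end = c(1200L, 1800L, 3000L), strand = strand,
                      stringsAsFactors = FALSE)
  gene_models_from(genes, exons)
}

test_that("introns are the gaps between consecutive exons", {
  gm <- std_models()
  intr <- derive_introns(gm)
  expect_equal(intr$start, c(1200L, 1800L))
  expect_equal(intr$end, c(1500L, 2600L))
  # union of exons and introns tiles the transcript span
  widths <- sum(gm$exons$end - gm$exons$start) + sum(intr$end - intr$start)
  expect_equal(widths, 3000L - 1000L)

  single <- gene_models_from(
    data.frame(gene_id = "G2", name = "G2", chrom = "chr1", start = 1L,
               end = 100L, strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = "G2", transcript_id = "T2", chrom = "chr1",
               start = 1L, end = 100L, strand = "+",
               stringsAsFactors = FALSE))
  expect_equal(nrow(derive_introns(single)), 0L)
})

test_that("location classes follow the mirtron > exonic > intronic > intergenic precedence", {
  gm <- std_models()
  m <- mirna_tbl(c("m_in", "m_ex", "m_mt", "m_ig"), "chr1",
                 start = c(1250L, 1190L, 1200L, 9000L),
                 end = c(1330L, 1260L, 1500L, 9080L),
                 strand = "+")
  ctx <- classify_location(m, gm)
  expect_equal(ctx$location_class,
               c("intronic", "exonic", "mirtron", "intergenic"))
  expect_equal(ctx$host_gene_ids, c("G1", "G1", "G1", ""))
  expect_equal(ctx$host_orientation[1], "sense")

  # antisense host orientation is recorded, class unchanged
  anti <- classify_location(mirna_tbl("m_a", "chr1", 1250L, 1330L, "-"), gm)
  expect_equal(anti$location_class, "intronic")
  expect_equal(anti$host_orientation, "antisense")
})

test_that("a precursor in introns of two overlapping genes lists both hosts", {
  genes <- data.frame(gene_id = c("PANKa", "PANKb"), name = c("PANKa", "PANKb"),
                      chrom = "chr1", start = c(1000L, 900L),
                      end = c(3000L, 2900L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = rep(c("PANKa", "PANKb"), each = 2),
    transcript_id = rep(c("Ta", "Tb"), each = 2),
    chrom = "chr1",
    start = c(1000L, 2000L, 900L, 2100L),
    end = c(1100L, 3000L, 1050L, 2900L),
    strand = rep(c("+", "-"), each = 2), stringsAsFactors = FALSE)
  ctx <- classify_location(mirna_tbl("m103", "chr1", 1300L, 1380L, "+"),
                           gene_models_from(genes, exons))
  expect_equal(ctx$location_class, "intronic")
  expect_equal(ctx$host_gene_ids, "PANKa,PANKb")
})

test_that("exon overlap in any transcript outranks intron containment", {
  # transcript T1 has an intron where transcript T2 has an exon
  genes <- data.frame(gene_id = "G1", name = "G1", chrom = "chr1",
                      start = 1000L, end = 3000L, strand = "+",
                      stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = "G1", transcript_id = c("T1", "T1", "T2", "T2"),
    chrom = "chr1",
    start = c(1000L, 2000L, 1000L, 1240L),
    end = c(1200L, 3000L, 1100L, 1600L),
    strand = "+", stringsAsFactors = FALSE)
  ctx <- classify_location(mirna_tbl("m", "chr1", 1250L, 1330L, "+"),
                           gene_models_from(genes, exons))
  expect_equal(ctx$location_class, "exonic")
})

test_that("unknown chromosome yields flagged intergenic with a warning", {
  expect_warning(
    ctx <- classify_location(mirna_tbl("m", "chrZ", 10L, 90L, "+"),
                             std_models()),
    "chrZ")
  expect_equal(ctx$location_class, "intergenic")
  expect_equal(ctx$flag, "unknown_chromosome")
})

test_that("cluster rule: same strand, consecutive gap strictly below the limit", {
  two <- mirna_tbl(c("a", "b"), "chr1", c(0L, 5100L), c(100L, 5200L), "+")
  expect_equal(cluster_sets(detect_clusters(two)), list(c("a", "b")))

  opp <- mirna_tbl(c("a", "b"), "chr1", c(0L, 5100L), c(100L, 5200L),
                   c("+", "-"))
  expect_equal(length(cluster_sets(detect_clusters(opp))), 0L)

  # boundary: gap of exactly 10,000 does not cluster
  edge <- mirna_tbl(c("a", "b"), "chr1", c(0L, 10100L), c(100L, 10200L), "+")
  expect_equal(length(cluster_sets(detect_clusters(edge))), 0L)
  just <- mirna_tbl(c("a", "b"), "chr1", c(0L, 10099L), c(100L, 10200L), "+")
  expect_equal(length(cluster_sets(detect_clusters(just))), 1L)

  # overlapping precursors (negative gap) cluster
  ovl <- mirna_tbl(c("a", "b"), "chr1", c(0L, 50L), c(100L, 150L), "+")
  expect_equal(cluster_sets(detect_clusters(ovl)), list(c("a", "b")))
})

test_that("chaining is single-linkage: A-B-C with pairwise gaps under 10 kb is one cluster", {
  abc <- mirna_tbl(c("A", "B", "C"), "chr1",
                   start = c(0L, 8100L, 16200L),
                   end = c(100L, 8200L, 16300L), strand = "+")
  got <- cluster_sets(detect_clusters(abc))
  expect_equal(got, list(c("A", "B", "C")))
  # oracle: brute-force transitive closure agrees
  expect_equal(sort_sets(got), sort_sets(brute_clusters(abc)))
})

test_that("cluster detection equals brute-force closure on random fixtures up to 200 genes", {
  set.seed(802)
  for (n in c(10, 50, 120, 200)) {
    fx <- random_mirna_fixture(n)
    expect_equal(sort_sets(cluster_sets(detect_clusters(fx))),
                 sort_sets(brute_clusters(fx)),
                 info = sprintf("n = %d", n))
  }
})

test_that("cluster membership is order-invariant and monotone in max_gap", {
  set.seed(903)
  fx <- random_mirna_fixture(80)
  base <- sort_sets(cluster_sets(detect_clusters(fx)))
  for (i in 1:3) {
    perm <- fx[sample(nrow(fx)), , drop = FALSE]
    expect_equal(sort_sets(cluster_sets(detect_clusters(perm))), base)
  }
  sizes <- function(gap) {
    sum(lengths(cluster_sets(detect_clusters(fx, max_gap = gap))))
  }
  gaps <- c(1000L, 5000L, 10000L, 50000L)
  expect_true(all(diff(vapply(gaps, sizes, numeric(1))) >= 0))
})

test_that("mature context aggregates classes and cluster membership over loci", {
  gm <- std_models()
  genes <- mirna_tbl(c("L1", "L2", "L3", "L4"), "chr1",
                     start = c(1250L, 50000L, 55000L, 200000L),
                     end = c(1330L, 50100L, 55100L, 200100L),
                     strand = "+")
  ctx <- annotate_context(genes, gm)
  # L2/L3 cluster (gap 4,900), L1 intronic, L4 intergenic singleton
  matures <- data.frame(
    mature_id = c("ma", "mb", "mc"),
    name = c("miR-single", "miR-dual", "miR-clustered"),
    sequence = NA_character_,
    gene_ids = c("L1", "L1,L4", "L2,L4"),
    stringsAsFactors = FALSE)
  mc <- mature_context(matures, ctx)
  expect_equal(mc$location_classes[1], "intronic")
  expect_false(mc$clustered[1])
  # multi-locus: intronic + intergenic set, like miR-378
  expect_equal(mc$location_classes[2], "intergenic,intronic")
  # clustered if ANY coding locus is clustered
  expect_true(mc$clustered[3])
  expect_match(mc$cluster_ids[3], "cluster_")

  bad <- data.frame(mature_id = "mx", name = "x", sequence = NA,
                    gene_ids = "NOPE", stringsAsFactors = FALSE)
  expect_error(mature_context(bad, ctx), "NOPE")
})

test_that("every miRNA gene receives exactly one location class", {
  cfg <- sim_config(seed = 11)
  anno <- simulate_annotation(cfg, tempfile())
  p <- read_mirna_gff(anno$mirna_gff)
  g <- read_gene_models(anno$gene_gtf, "gtf")
  ctx <- classify_location(p$genes, g)
  expect_equal(nrow(ctx), nrow(p$genes))
  expect_true(all(ctx$location_class %in%
                    c("intergenic", "intronic", "exonic", "mirtron")))
})
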