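test_that("config validation enforces the generator's invariants", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(1, class_fractions = c(intergenic = 0.5,
                                                 intronic = 0.4,
                                                 exonic = 0.2,
                                                 mirtron = 0.1)),
               "sum to 1")
  expect_error(sim_config(1, cluster_gap_range = c(2000, 12000)),
               "max_gap")
  expect_error(sim_config(1, block_sizes = c(100, 100)), "core")
  expect_error(sim_config(1, qpcr_pairs = data.frame(
    gene = "G", mirna = "m", r_target = 1.2)), "(-1, 1)")
})

test_that("the generator is deterministic: same seed, byte-identical files", {
  cfg <- sim_config(seed = 7)
  a1 <- simulate_annotation(cfg, tempfile())
  a2 <- simulate_annotation(cfg, tempfile())
  expect_identical(readLines(a1$mirna_gff), readLines(a2$mirna_gff))
  expect_identical(readLines(a1$gene_gtf), readLines(a2$gene_gtf))
  e1 <- simulate_expression(cfg, tempfile())
  e2 <- simulate_expression(cfg, tempfile())
  expect_identical(readLines(e1$matrix_tsv), readLines(e2$matrix_tsv))
  q1 <- simulate_qpcr(cfg, tempfile())
  q2 <- simulate_qpcr(cfg, tempfile())
  expect_identical(readLines(q1$ct_tsv), readLines(q2$ct_tsv))
  # a different seed changes the output
  e3 <- simulate_expression(sim_config(seed = 8), tempfile())
  expect_false(identical(readLines(e1$matrix_tsv),
                         readLines(e3$matrix_tsv)))
})

test_that("emitted files parse cleanly through the readers", {
  cfg <- sim_config(seed = 21)
  anno <- simulate_annotation(cfg, tempfile())
  expect_no_warning(p <- read_mirna_gff(anno$mirna_gff))
  expect_no_warning(g <- read_gene_models(anno$gene_gtf, "gtf"))
  expect_equal(nrow(p$genes), cfg$n_mirna_genes)
  expect_true(all(p$genes$end > p$genes$start))

  ex <- simulate_expression(cfg, tempfile())
  expect_no_warning(d <- read_expression(ex$matrix_tsv,
                                         ex$sample_sheet_tsv))
  expect_equal(dim(d$matrix), c(cfg$n_mirna, 24L))

  q <- simulate_qpcr(cfg, tempfile())
  expect_no_warning(ct <- read_qpcr(q$ct_tsv))
  expect_equal(length(unique(ct$sample_id)), 12L)
})

test_that("planted multi-locus matures appear in the annotation", {
  anno <- simulate_annotation(sim_config(seed = 33), tempfile())
  p <- read_mirna_gff(anno$mirna_gff)
  multi <- p$matures[grepl(",", p$matures$gene_ids), ]
  expect_gte(nrow(multi), 2L)
  ctx <- annotate_context(p$genes, read_gene_models(anno$gene_gtf, "gtf"))
  mc <- mature_context(p$matures, ctx)
  # one planted mature combines an intronic and an intergenic locus
  expect_true(any(mc$location_classes == "intergenic,intronic"))
  # one planted mature sits in two different genomic clusters
  n_cl <- vapply(strsplit(mc$cluster_ids, ","),
                 function(x) length(setdiff(x, "")), integer(1))
  expect_true(any(n_cl >= 2L))
})

test_that("zeroed individuals exclude a miRNA from the core set", {
  cfg <- sim_config(seed = 13)
  ex <- simulate_expression(cfg, tempfile())
  d <- read_expression(ex$matrix_tsv, ex$sample_sheet_tsv)
  nm <- normalize_percentile(d$matrix)
  core <- detect_core(nm, d$samples)
  tr <- ex$truth$mirnas
  # every miRNA zeroed for >= 1 individual is out; all others are in
  expect_setequal(core$core, tr$mirna[tr$core])
  zeroed <- tr$mirna[!tr$core][1]
  ids <- strsplit(tr$zeroed_individuals[tr$mirna == zeroed], ",")[[1]]
  cols <- d$samples$sample_id[d$samples$individual_id %in% ids]
  expect_true(all(is.na(nm[zeroed, cols])))
})

test_that("qPCR coupling targets are recovered within sampling tolerance", {
  cfg <- sim_config(seed = 55,
                    qpcr_pairs = data.frame(gene = "GENE1",
                                            mirna = "miR-1",
                                            r_target = 0.9,
                                            stringsAsFactors = FALSE),
                    replicate_sd = 0.1)
  q <- simulate_qpcr(cfg, tempfile())
  agg <- aggregate_replicates(read_qpcr(q$ct_tsv))
  res <- qpcr_host_correlation(agg$ct, cfg$qpcr_pairs,
                               mirna_ref = cfg$mirna_ref,
                               gene_ref = cfg$gene_ref)
  expect_gte(res$r, 0.8)
  expect_lte(res$r, 0.97)

  # zero replicate noise: aggregated means equal the planted values
  cfg0 <- sim_config(seed = 56, replicate_sd = 0)
  q0 <- simulate_qpcr(cfg0, tempfile())
  ct0 <- read_qpcr(q0$ct_tsv)
  agg0 <- aggregate_replicates(ct0)$ct
  first <- ct0[ct0$replicate == 1, ]
  expect_equal(agg0$ct_mean[order(agg0$sample_id, agg0$assay)],
               first$ct[order(first$sample_id, first$assay)],
               tolerance = 1e-9)
})

test_that("null qPCR coupling yields weak observed correlations across seeds", {
  # at rho = 0 and n = 12, P(|r| < 0.6) is ~0.96; asserting >= 0.90 over
  # 40 seeds leaves headroom for Monte-Carlo error of the check itself
  rs <- vapply(1:40, function(s) {
    cfg <- sim_config(seed = 1000 + s,
                      qpcr_pairs = data.frame(gene = "GENE1",
                                              mirna = "miR-1",
                                              r_target = 0,
                                              stringsAsFactors = FALSE))
    q <- simulate_qpcr(cfg, tempfile())
    agg <- aggregate_replicates(read_qpcr(q$ct_tsv))
    qpcr_host_correlation(agg$ct, cfg$qpcr_pairs)$r
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.6), 0.90)
})
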