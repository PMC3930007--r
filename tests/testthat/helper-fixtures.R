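# Shared fixture builders and independent oracles.

tsv_line <- function(...) paste(..., sep = "\t")

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# miRNA GFF3 from a data.frame with 1-BASED inclusive coordinates
# (gene_id, name, chrom, start1, end1, strand) and optional matures
# (mature_id, name, gene_id, start1, end1).
make_mirna_gff <- function(genes, matures = NULL) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, tsv_line(
      g$chrom, ".", "miRNA_primary_transcript", g$start1, g$end1, ".",
      g$strand, ".", sprintf("ID=%s;Name=%s", g$gene_id, g$name)))
  }
  if (!is.null(matures)) {
    for (i in seq_len(nrow(matures))) {
      m <- matures[i, ]
      g <- genes[genes$gene_id == m$gene_id, ]
      lines <- c(lines, tsv_line(
        g$chrom, ".", "miRNA", m$start1, m$end1, ".", g$strand, ".",
        sprintf("ID=%s;Name=%s;Derives_from=%s", m$mature_id, m$name,
                m$gene_id)))
    }
  }
  write_tmp(lines, ".gff3")
}

# one-transcript-per-gene GFF3 gene models; exons is a list keyed by
# gene_id of matrices/data.frames with 1-based start1/end1
make_gene_gff3 <- function(genes, exons) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- paste0("t_", g$gene_id)
    lines <- c(lines,
      tsv_line(g$chrom, ".", "gene", g$start1, g$end1, ".", g$strand, ".",
               sprintf("ID=%s;Name=%s", g$gene_id, g$gene_id)),
      tsv_line(g$chrom, ".", "mRNA", g$start1, g$end1, ".", g$strand, ".",
               sprintf("ID=%s;Parent=%s", tid, g$gene_id)))
    ex <- exons[[g$gene_id]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, tsv_line(
        g$chrom, ".", "exon", ex$start1[j], ex$end1[j], ".", g$strand,
        ".", sprintf("ID=%s_e%d;Parent=%s", tid, j, tid)))
    }
  }
  write_tmp(lines, ".gff3")
}

# gene models straight from 0-based internal tables (skips file round trip)
gene_models_from <- function(genes, exons) {
  list(genes = genes, exons = exons)
}

# quick builder for miRNA gene tables in internal coordinates
mirna_tbl <- function(gene_id, chrom, start, end, strand,
                      name = gene_id) {
  data.frame(gene_id = gene_id, name = name, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

# --- independent oracles ---------------------------------------------------

# brute-force transitive closure of the pairwise same-strand <max_gap
# relation; returns a list of sorted member vectors (size >= 2)
brute_clusters <- function(genes, max_gap = 10000L) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (genes$chrom[i] != genes$chrom[j]) next
    if (genes$strand[i] != genes$strand[j]) next
    gap <- max(genes$start[i], genes$start[j]) -
      min(genes$end[i], genes$end[j])
    if (gap < max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(genes$gene_id, roots)
  comps <- comps[vapply(comps, length, integer(1)) >= 2L]
  unname(lapply(comps, sort))
}

# membership sets from a detect_clusters() result, sorted for comparison
cluster_sets <- function(cs) {
  m <- cs$membership[!is.na(cs$membership$cluster_id), , drop = FALSE]
  unname(lapply(split(m$gene_id, m$cluster_id), sort))
}

sort_sets <- function(sets) {
  sets[order(vapply(sets, function(s) s[1], character(1)))]
}

# brute-force hypergeometric right tail from binomial coefficients
hyper_tail_brute <- function(k, n, m, N) {
  kk <- k:min(n, m)
  sum(choose(m, kk) * choose(N - m, n - kk)) / choose(N, n)
}

# random miRNA gene fixture for cluster property tests
random_mirna_fixture <- function(n) {
  mirna_tbl(
    gene_id = sprintf("M%03d", seq_len(n)),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = st <- sort(sample(0:500000, n)),
    end = st + sample(80:120, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE))
}
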