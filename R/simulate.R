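#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with defaults emulating the study
#' design the package is modelled on: eight individuals sampled at three
#' time points (24 arrays), a 155-miRNA tissue core among 224 detected
#' miRNAs, a location mix dominated by intergenic and intronic loci with
#' rare exonic and mirtron cases, genomic clusters with member gaps below
#' 10 kb, co-expression blocks whose sizes follow the six observed
#' relevance networks (14, 12, 2, 2, 2, 2), a power-law mean-CV relation
#' (`mean = a * CV^b`) with log-normal scatter, and qPCR host/miRNA
#' couplings at n = 12 with three technical replicates.
#'
#' @param seed integer seed; mandatory, all generator randomness flows
#'   from it.
#' @param n_chromosomes chromosomes to spread annotation over.
#' @param n_mirna_genes planted miRNA precursor loci.
#' @param class_fractions named fractions (intergenic, intronic, exonic,
#'   mirtron) summing to 1; converted to counts with at least one locus
#'   per class.
#' @param cluster_sizes planted cluster sizes (members are taken from the
#'   intergenic allotment).
#' @param cluster_gap_range member gap range in bp, strictly below 10 kb.
#' @param n_background_genes protein-coding genes hosting no miRNA.
#' @param exons_per_gene exons per gene model.
#' @param mirna_width_range precursor width range in bp.
#' @param max_gap clustering distance limit the geometry must respect.
#' @param n_individuals,n_timepoints expression design (8 x 3 = 24
#'   samples).
#' @param n_mirna,n_core detected and core miRNA counts.
#' @param block_sizes planted co-expression block sizes (within core).
#' @param block_r target within-block Pearson correlation.
#' @param power_a,power_b,power_sigma power-law coefficient, exponent and
#'   log-normal noise SD of the mean-CV relation.
#' @param cv_range,block_cv_range CV draw ranges (log-uniform); block
#'   members use the narrower range so their variation is coherent rather
#'   than near-constant or wild.
#' @param base_log2 log2 intensity of a miRNA at mean ratio 1 (array
#'   brightness anchor).
#' @param qpcr_pairs data.frame (`gene`, `mirna`, `r_target`) of planted
#'   host/miRNA couplings.
#' @param n_qpcr_individuals,n_qpcr_timepoints qPCR design (6 x 2 = 12).
#' @param n_replicates technical replicates per reaction.
#' @param replicate_sd replicate noise SD in cycles.
#' @param ref_sd reference-assay Ct SD in cycles (references are
#'   near-constant).
#' @param mirna_ref,gene_ref reference assay names.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 3L,
                       n_mirna_genes = 155L,
                       class_fractions = c(intergenic = 0.613,
                                           intronic = 0.368,
                                           exonic = 0.013,
                                           mirtron = 0.006),
                       cluster_sizes = c(6L, 3L, 3L, 2L, 2L, 2L),
                       cluster_gap_range = c(2000L, 8000L),
                       n_background_genes = 10L,
                       exons_per_gene = 3L,
                       mirna_width_range = c(70L, 110L),
                       max_gap = 10000L,
                       n_individuals = 8L,
                       n_timepoints = 3L,
                       n_mirna = 224L,
                       n_core = 155L,
                       block_sizes = c(14L, 12L, 2L, 2L, 2L, 2L),
                       block_r = 0.99,
                       power_a = 0.5967,
                       power_b = -0.999,
                       power_sigma = 0.2,
                       cv_range = c(0.05, 1.9),
                       block_cv_range = c(0.2, 0.8),
                       base_log2 = 8,
                       qpcr_pairs = data.frame(
                         gene = c("EP300", "PPARGC1B", "SREBF2", "PTK2"),
                         mirna = c("bta-miR-1281", "bta-miR-378",
                                   "bta-miR-33a", "bta-miR-151-5p"),
                         r_target = c(0.624, 0.193, 0.635, 0.001),
                         stringsAsFactors = FALSE),
                       n_qpcr_individuals = 6L,
                       n_qpcr_timepoints = 2L,
                       n_replicates = 3L,
                       replicate_sd = 0.15,
                       ref_sd = 0.1,
                       mirna_ref = "bta-miR-181a",
                       gene_ref = "ACTB") {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stopf("sim_config requires an explicit seed")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (abs(sum(class_fractions) - 1) > 1e-6) {
    stopf("class_fractions must sum to 1")
  }
  need <- c("intergenic", "intronic", "exonic", "mirtron")
  if (!setequal(names(class_fractions), need)) {
    stopf("class_fractions must be named: %s", paste(need, collapse = ", "))
  }
  if (any(cluster_sizes < 2L)) stopf("cluster sizes must be >= 2")
  if (cluster_gap_range[2] >= max_gap) {
    stopf("cluster gaps must stay strictly below max_gap (%d bp)", max_gap)
  }
  if (sum(block_sizes) > n_core) {
    stopf("block sizes exceed the core miRNA count")
  }
  if (n_core > n_mirna) stopf("n_core cannot exceed n_mirna")
  if (any(abs(qpcr_pairs$r_target) >= 1)) {
    stopf("qPCR coupling targets must lie in (-1, 1)")
  }
  class_counts <- round(class_fractions * n_mirna_genes)
  class_counts[class_counts == 0L] <- 1L
  class_counts["intergenic"] <- class_counts["intergenic"] +
    (n_mirna_genes - sum(class_counts))
  if (sum(cluster_sizes) > class_counts["intergenic"]) {
    stopf("cluster members exceed the intergenic allotment")
  }
  cfg$class_counts <- class_counts
  structure(cfg, class = "sim_config")
}

#' Simulate a miRNA annotation with known genomic context
#'
#' Emits a miRBase-dialect miRNA GFF3 and a protein-coding GTF whose
#' geometry realizes the planted location classes exactly: mirtrons span
#' an intron end-to-end, exonic precursors overlap an exon by >= 1 bp,
#' intronic precursors sit strictly inside an intron, intergenic
#' precursors lie farther than `max_gap` from every gene and every other
#' miRNA unless they belong to a planted cluster (member gaps drawn below
#' 10 kb on a shared strand).  Two mature miRNAs are planted at two loci
#' each: one coded at an intronic and an intergenic precursor, and one
#' coded inside two different clusters.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list: `mirna_gff`, `gene_gtf` (paths) and `truth`, a data.frame
#'   with the planted `location_class`, `host_gene_ids` and `cluster`
#'   per precursor, plus `mature_name` links.
#' @export
simulate_annotation <- function(config, dir = tempfile("simanno")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    cc <- config$class_counts
    n_clustered <- sum(config$cluster_sizes)
    n_single_intergenic <- cc["intergenic"] - n_clustered

    units <- c(
      rep("intronic", cc["intronic"]),
      rep("exonic", cc["exonic"]),
      rep("mirtron", cc["mirtron"]),
      rep("intergenic", n_single_intergenic),
      paste0("cluster", seq_along(config$cluster_sizes)),
      rep("gene_only", config$n_background_genes))
    units <- sample(units)

    chrom_of <- rep_len(paste0("chr", seq_len(config$n_chromosomes)),
                        length(units))
    cursor <- stats::setNames(rep(10000L, config$n_chromosomes),
                              paste0("chr", seq_len(config$n_chromosomes)))

    mirna_rows <- list(); gene_rows <- list(); exon_rows <- list()
    truth <- list()
    mi <- 0L; gi <- 0L

    mirna_w <- function() {
      sample(seq(config$mirna_width_range[1], config$mirna_width_range[2]),
             1)
    }

    add_gene <- function(chrom, at, strand, intron_widths) {
      # alternating exon/intron layout from `at`
      gi <<- gi + 1L
      g <- sprintf("SYNG%04d", gi)
      t <- sprintf("SYNT%04d", gi)
      exw <- sample(150:300, config$exons_per_gene, replace = TRUE)
      pos <- at
      ex <- list()
      for (e in seq_len(config$exons_per_gene)) {
        ex[[e]] <- c(pos, pos + exw[e])
        pos <- pos + exw[e]
        if (e < config$exons_per_gene) pos <- pos + intron_widths[e]
      }
      gene_rows[[g]] <<- data.frame(
        gene_id = g, transcript_id = t, chrom = chrom,
        start = ex[[1]][1], end = ex[[length(ex)]][2], strand = strand,
        stringsAsFactors = FALSE)
      exon_rows[[g]] <<- do.call(rbind, lapply(ex, function(b) {
        data.frame(gene_id = g, transcript_id = t, chrom = chrom,
                   start = b[1], end = b[2], strand = strand,
                   stringsAsFactors = FALSE)
      }))
      list(gene_id = g,
           introns = lapply(seq_len(config$exons_per_gene - 1L),
                            function(e) c(ex[[e]][2], ex[[e + 1L]][1])))
    }

    add_mirna <- function(chrom, start, width, strand, class, hosts,
                          cluster) {
      mi <<- mi + 1L
      id <- sprintf("SYNMI%03d", mi)
      mirna_rows[[id]] <<- data.frame(
        gene_id = id, name = sprintf("syn-mir-%03d", mi), chrom = chrom,
        start = start, end = start + width, strand = strand,
        stringsAsFactors = FALSE)
      truth[[id]] <<- data.frame(
        gene_id = id, location_class = class,
        host_gene_ids = paste(hosts, collapse = ","),
        cluster = cluster, chrom = chrom, strand = strand,
        stringsAsFactors = FALSE)
      id
    }

    for (u in seq_along(units)) {
      unit <- units[u]; chrom <- chrom_of[u]
      at <- cursor[chrom]
      gstrand <- sample(c("+", "-"), 1)
      span_end <- at
      if (unit %in% c("intronic", "exonic", "mirtron", "gene_only")) {
        w <- mirna_w()
        margin <- sample(60:400, 2, replace = TRUE)
        n_introns <- max(1L, config$exons_per_gene - 1L)
        iw <- c(if (unit == "mirtron") w else w + sum(margin),
                sample(1500:4000, n_introns, replace = TRUE))
        iw <- iw[seq_len(n_introns)]
        gm <- add_gene(chrom, at, gstrand, iw)
        intron1 <- gm$introns[[1]]
        if (unit == "intronic") {
          mstrand <- sample(c("+", "-"), 1)
          add_mirna(chrom, intron1[1] + margin[1], w, mstrand, "intronic",
                    gm$gene_id, NA_character_)
        } else if (unit == "mirtron") {
          add_mirna(chrom, intron1[1], w, gstrand, "mirtron",
                    gm$gene_id, NA_character_)
        } else if (unit == "exonic") {
          # straddle the start of exon 2 (inside intron 1 otherwise)
          ov <- sample(10:40, 1)
          mstrand <- sample(c("+", "-"), 1)
          add_mirna(chrom, intron1[2] - (w - ov), w, mstrand, "exonic",
                    gm$gene_id, NA_character_)
        }
        span_end <- gene_rows[[gm$gene_id]]$end
      } else if (unit == "intergenic") {
        w <- mirna_w()
        add_mirna(chrom, at, w, sample(c("+", "-"), 1), "intergenic",
                  character(0), NA_character_)
        span_end <- at + w
      } else {
        ci <- as.integer(sub("cluster", "", unit))
        k <- config$cluster_sizes[ci]
        strand <- sample(c("+", "-"), 1)
        pos <- at
        for (j in seq_len(k)) {
          w <- mirna_w()
          add_mirna(chrom, pos, w, strand, "intergenic", character(0),
                    paste0("planted_", ci))
          pos <- pos + w + sample(
            seq(config$cluster_gap_range[1], config$cluster_gap_range[2]),
            1)
        }
        span_end <- pos
      }
      cursor[chrom] <- span_end + config$max_gap +
        sample(2000:6000, 1)
    }

    mirna <- do.call(rbind, mirna_rows); rownames(mirna) <- NULL
    genes <- do.call(rbind, gene_rows); rownames(genes) <- NULL
    exons <- do.call(rbind, exon_rows); rownames(exons) <- NULL
    truth <- do.call(rbind, truth); rownames(truth) <- NULL

    # mature products: one per precursor; plant two multi-locus matures
    mature_name <- sprintf("syn-miR-%03d", seq_len(nrow(mirna)))
    intronic_ids <- truth$gene_id[truth$location_class == "intronic"]
    single_inter <- truth$gene_id[truth$location_class == "intergenic" &
                                    is.na(truth$cluster)]
    if (length(intronic_ids) > 0L && length(single_inter) > 0L) {
      # one mature coded at an intronic and an intergenic locus
      a <- match(intronic_ids[1], truth$gene_id)
      b <- match(single_inter[1], truth$gene_id)
      mature_name[b] <- mature_name[a]
    }
    cl <- unique(truth$cluster[!is.na(truth$cluster)])
    if (length(cl) >= 2L) {
      # one mature coded inside two different clusters
      a <- which(truth$cluster == cl[1])[1]
      b <- which(truth$cluster == cl[2])[1]
      mature_name[b] <- mature_name[a]
    }
    truth$mature_name <- mature_name

    gff <- file.path(dir, "mirna.gff3")
    gtf <- file.path(dir, "genes.gtf")
    write_mirna_gff3(mirna, mature_name, gff)
    write_gene_gtf(genes, exons, gtf)
    list(mirna_gff = gff, gene_gtf = gtf, truth = truth)
  })
}

write_mirna_gff3 <- function(mirna, mature_name, path) {
  ord <- order(mirna$chrom, mirna$start)
  lines <- c("##gff-version 3")
  for (i in ord) {
    lines <- c(lines, paste(
      mirna$chrom[i], "simulated", "miRNA_primary_transcript",
      from0(mirna$start[i]), mirna$end[i], ".", mirna$strand[i], ".",
      sprintf("ID=%s;Name=%s", mirna$gene_id[i], mirna$name[i]),
      sep = "\t"))
    # mature record nested 10 nt into the precursor, 22 nt long
    ms <- mirna$start[i] + 10L
    lines <- c(lines, paste(
      mirna$chrom[i], "simulated", "miRNA", from0(ms), ms + 22L, ".",
      mirna$strand[i], ".",
      sprintf("ID=MIMAT%s;Name=%s;Derives_from=%s",
              sub("SYNMI", "", mirna$gene_id[i]), mature_name[i],
              mirna$gene_id[i]),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

write_gene_gtf <- function(genes, exons, path) {
  lines <- character(0)
  ord <- order(genes$chrom, genes$start)
  for (i in ord) {
    g <- genes[i, ]
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_id)
    lines <- c(lines, paste(g$chrom, "simulated", "gene", from0(g$start),
                            g$end, ".", g$strand, ".", attr_g, sep = "\t"))
    lines <- c(lines, paste(
      g$chrom, "simulated", "transcript", from0(g$start), g$end, ".",
      g$strand, ".",
      sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id,
              g$transcript_id), sep = "\t"))
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        ex$chrom[j], "simulated", "exon", from0(ex$start[j]), ex$end[j],
        ".", ex$strand[j], ".",
        sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id[j],
                ex$transcript_id[j]), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an expression matrix with planted structure
#'
#' Generates raw intensities for `n_mirna` miRNAs over
#' `n_individuals * n_timepoints` samples.  Per miRNA, a coefficient of
#' variation is drawn log-uniformly and the linear-scale mean follows the
#' planted power law `mean = a * CV^b` with multiplicative log-normal
#' noise; sample values are log-normal with exactly that mean and CV.
#' Co-expression blocks share a per-sample latent factor so the planted
#' within-block correlation is `block_r` (analytic noise ratio
#' construction).  Non-core miRNAs are zeroed (undetected) for all
#' samples of one or more randomly chosen individuals, giving core-rule
#' negative controls; core miRNAs are detected everywhere.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return list: `matrix_tsv`, `sample_sheet_tsv` (paths) and `truth`
#'   (list with per-miRNA data.frame `mirnas`, the planted `blocks`,
#'   `a`, `b`, `sigma`).
#' @export
simulate_expression <- function(config, dir = tempfile("simexpr")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed + 1L, {
    n_s <- config$n_individuals * config$n_timepoints
    samples <- data.frame(
      sample_id = sprintf("S%02d", seq_len(n_s)),
      individual_id = rep(sprintf("steer%d", seq_len(config$n_individuals)),
                          each = config$n_timepoints),
      time_point = rep(sprintf("t%d", seq_len(config$n_timepoints)),
                       times = config$n_individuals),
      group = rep(c("control", "highfat"),
                  each = config$n_timepoints *
                    ceiling(config$n_individuals / 2))[seq_len(n_s)],
      stringsAsFactors = FALSE)

    n <- config$n_mirna
    mirnas <- sprintf("syn-miR-%03d", seq_len(n))
    core <- seq_len(config$n_core)

    block_id <- rep(NA_integer_, n)
    off <- 0L
    for (bi in seq_along(config$block_sizes)) {
      block_id[core[off + seq_len(config$block_sizes[bi])]] <- bi
      off <- off + config$block_sizes[bi]
    }

    lu <- function(n, range) {
      exp(stats::runif(n, log(range[1]), log(range[2])))
    }
    cv <- ifelse(is.na(block_id),
                 lu(n, config$cv_range),
                 lu(n, config$block_cv_range))
    mean_lin <- config$power_a * cv^config$power_b *
      exp(stats::rnorm(n, 0, config$power_sigma))
    s_log <- sqrt(log(1 + cv^2))
    mu_log <- log(mean_lin) - s_log^2 / 2

    z <- matrix(stats::rnorm(length(config$block_sizes) * n_s),
                nrow = length(config$block_sizes))
    eps <- matrix(stats::rnorm(n * n_s), nrow = n)
    f <- eps
    in_block <- !is.na(block_id)
    f[in_block, ] <- sqrt(config$block_r) * z[block_id[in_block], ] +
      sqrt(1 - config$block_r) * eps[in_block, ]

    lin <- exp(mu_log + s_log * f)          # linear ratio scale
    raw <- 2^config$base_log2 * lin         # raw intensity scale

    zeroed <- vector("list", n)
    noncore <- setdiff(seq_len(n), core)
    for (i in noncore) {
      k <- sample(1:3, 1)
      ids <- sample(sprintf("steer%d", seq_len(config$n_individuals)), k)
      zeroed[[i]] <- sort(ids)
      raw[i, samples$individual_id %in% ids] <- 0
    }

    dimnames(raw) <- list(mirnas, samples$sample_id)
    mat_path <- file.path(dir, "intensity.tsv")
    sheet_path <- file.path(dir, "samples.tsv")
    utils::write.table(
      data.frame(mirna = mirnas, signif(raw, 8), check.names = FALSE,
                 stringsAsFactors = FALSE),
      mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(samples, sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    truth <- list(
      mirnas = data.frame(
        mirna = mirnas, core = seq_len(n) %in% core, block = block_id,
        cv = cv, mean = mean_lin,
        zeroed_individuals = cjoin(lapply(zeroed, function(x)
          if (is.null(x)) character(0) else x)),
        stringsAsFactors = FALSE),
      blocks = lapply(seq_along(config$block_sizes), function(bi) {
        sort(mirnas[which(block_id == bi)])
      }),
      a = config$power_a, b = config$power_b, sigma = config$power_sigma)
    list(matrix_tsv = mat_path, sample_sheet_tsv = sheet_path,
         truth = truth)
  })
}

#' Draw mean/CV points from a planted power law
#'
#' Convenience generator for testing the power fit in isolation: CVs are
#' log-uniform over `cv_range` and means follow `a * CV^b` with
#' multiplicative log-normal noise of SD `sigma` (in log units,
#' `sigma = 0` gives exact power-law data).
#'
#' @param n number of points.
#' @param a,b planted coefficient and exponent.
#' @param sigma log-normal noise SD.
#' @param cv_range CV range.
#' @param seed optional seed (uses the current RNG stream when NULL).
#' @return data.frame with columns `mean`, `cv` usable by [fit_power()].
#' @export
simulate_power_points <- function(n = 150L, a = 0.5967, b = -0.999,
                                  sigma = 0.2, cv_range = c(0.05, 1.9),
                                  seed = NULL) {
  gen <- function() {
    cv <- exp(stats::runif(n, log(cv_range[1]), log(cv_range[2])))
    data.frame(mean = a * cv^b * exp(stats::rnorm(n, 0, sigma)), cv = cv)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a qPCR Ct table with planted host/miRNA coupling
#'
#' Twelve samples (six individuals at two ages by default).  Each planted
#' (gene, miRNA) pair shares a per-sample latent factor scaled so the
#' expression correlation equals its target R; Ct values are the latent
#' expression mapped to cycles (lower Ct = higher expression, ~1.5 cycles
#' per SD) plus technical replicate noise.  Reference assays are
#' near-constant across samples, emulating stably expressed
#' normalizers.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return list: `ct_tsv` (path), `truth` (the pair table with planted
#'   `r_target` and the per-assay planted Ct means).
#' @export
simulate_qpcr <- function(config, dir = tempfile("simqpcr")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed + 2L, {
    n_s <- config$n_qpcr_individuals * config$n_qpcr_timepoints
    sample_ids <- sprintf("Q%02d", seq_len(n_s))
    spread <- 1.5
    rows <- list()
    add_assay <- function(assay, ct_per_sample) {
      for (s in seq_len(n_s)) {
        reps <- ct_per_sample[s] +
          stats::rnorm(config$n_replicates, 0, config$replicate_sd)
        rows[[length(rows) + 1L]] <<- data.frame(
          sample_id = sample_ids[s], assay = assay,
          replicate = seq_len(config$n_replicates),
          ct = round(reps, 4), stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(config$qpcr_pairs))) {
      r <- config$qpcr_pairs$r_target[i]
      x <- stats::rnorm(n_s)
      y <- r * x + sqrt(1 - r^2) * stats::rnorm(n_s)
      add_assay(config$qpcr_pairs$gene[i], 24 - spread * x)
      add_assay(config$qpcr_pairs$mirna[i], 27 - spread * y)
    }
    add_assay(config$gene_ref, 18 + stats::rnorm(n_s, 0, config$ref_sd))
    add_assay(config$mirna_ref, 20 + stats::rnorm(n_s, 0, config$ref_sd))
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    path <- file.path(dir, "qpcr_ct.tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(ct_tsv = path,
         truth = list(pairs = config$qpcr_pairs,
                      gene_ref = config$gene_ref,
                      mirna_ref = config$mirna_ref))
  })
}
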