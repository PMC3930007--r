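#' Derive introns from gene models
#'
#' Introns are the gaps between consecutive exons of a transcript; a
#' transcript with one exon has none.
#'
#' @param gene_models result of [read_gene_models()].
#' @param gene_id optional gene to restrict to.
#' @return data.frame: `gene_id`, `transcript_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
derive_introns <- function(gene_models, gene_id = NULL) {
  ex <- gene_models$exons
  if (!is.null(gene_id)) ex <- ex[ex$gene_id %in% gene_id, , drop = FALSE]
  out <- list()
  for (tid in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) next
    out[[tid]] <- data.frame(
      gene_id = e$gene_id[1],
      transcript_id = tid,
      chrom = e$chrom[1],
      start = e$end[-nrow(e)],
      end = e$start[-1],
      strand = e$strand[1],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify miRNA genes by genomic location
#'
#' Each precursor is classified relative to protein-coding gene models with
#' precedence mirtron > exonic > intronic > intergenic:
#' \itemize{
#'   \item \strong{mirtron}: the precursor spans the entire length of an
#'     intron (boundaries equal within `mirtron_tolerance` nt);
#'   \item \strong{exonic}: >= 1 bp overlap with any exon;
#'   \item \strong{intronic}: fully inside an intron, no exon overlap;
#'   \item \strong{intergenic}: none of the above.
#' }
#' Precedence applies across all transcripts of all genes, so a precursor
#' inside an intron of one transcript but overlapping an exon of another is
#' exonic.  All qualifying host genes are listed; host orientation is
#' `sense` when the precursor and host share a strand, else `antisense`.
#' A precursor on a chromosome absent from the gene models is classified
#' intergenic with `flag = "unknown_chromosome"` and a warning.
#'
#' @param mirna_genes `genes` data.frame from [read_mirna_gff()].
#' @param gene_models result of [read_gene_models()].
#' @param mirtron_tolerance boundary slack in nt for the mirtron test
#'   (default 0: precursor must coincide exactly with an intron).
#' @return data.frame: `gene_id`, `name`, `chrom`, `start`, `end`, `strand`,
#'   `location_class`, `host_gene_ids`, `host_orientation` (comma-joined,
#'   aligned with hosts), `flag`.
#' @export
classify_location <- function(mirna_genes, gene_models,
                              mirtron_tolerance = 0L) {
  genes <- gene_models$genes
  exons <- gene_models$exons
  introns <- derive_introns(gene_models)
  known_chrom <- unique(genes$chrom)

  n <- nrow(mirna_genes)
  cls <- character(n); hosts <- character(n)
  orient <- character(n); flag <- character(n)

  for (i in seq_len(n)) {
    m <- mirna_genes[i, ]
    if (!(m$chrom %in% known_chrom)) {
      warnf("precursor %s on chromosome %s absent from gene models; %s",
            m$gene_id, m$chrom, "classified intergenic")
      cls[i] <- "intergenic"; hosts[i] <- ""; orient[i] <- ""
      flag[i] <- "unknown_chromosome"
      next
    }
    intr <- introns[introns$chrom == m$chrom, , drop = FALSE]
    ex <- exons[exons$chrom == m$chrom, , drop = FALSE]

    mir_hosts <- unique(intr$gene_id[
      abs(intr$start - m$start) <= mirtron_tolerance &
      abs(intr$end - m$end) <= mirtron_tolerance])
    exo_hosts <- unique(ex$gene_id[overlaps(m$start, m$end, ex$start, ex$end)])
    int_hosts <- unique(intr$gene_id[
      contained_in(m$start, m$end, intr$start, intr$end)])

    if (length(mir_hosts) > 0L) {
      cls[i] <- "mirtron"; h <- mir_hosts
    } else if (length(exo_hosts) > 0L) {
      cls[i] <- "exonic"; h <- exo_hosts
    } else if (length(int_hosts) > 0L) {
      cls[i] <- "intronic"; h <- int_hosts
    } else {
      cls[i] <- "intergenic"; h <- character(0)
    }
    h <- sort(h)
    hosts[i] <- paste(h, collapse = ",")
    orient[i] <- paste(ifelse(
      genes$strand[match(h, genes$gene_id)] == m$strand,
      "sense", "antisense"), collapse = ",")
    flag[i] <- ""
  }

  data.frame(gene_id = mirna_genes$gene_id, name = mirna_genes$name,
             chrom = mirna_genes$chrom, start = mirna_genes$start,
             end = mirna_genes$end, strand = mirna_genes$strand,
             location_class = cls, host_gene_ids = hosts,
             host_orientation = orient, flag = flag,
             stringsAsFactors = FALSE)
}

#' Detect genomic miRNA clusters
#'
#' Clusters are maximal chains of miRNA genes on the same chromosome and
#' strand in which the distance between consecutive precursors
#' (`next start - previous end`) is strictly less than `max_gap`
#' (single-linkage, so a chain A-B-C with pairwise gaps under the limit is
#' one cluster even when A and C are farther apart).  Overlapping
#' precursors (negative gap) cluster.  Chains of size >= 2 are reported;
#' singletons are non-clustered.
#'
#' @param mirna_genes `genes` data.frame from [read_mirna_gff()].
#' @param max_gap distance limit in bp (default 10000; a gap of exactly
#'   `max_gap` does not cluster).
#' @return list of class `cluster_set` with
#'   \describe{
#'     \item{clusters}{data.frame: `cluster_id`, `chrom`, `strand`,
#'       `start`, `end` (span), `n_members`, `members` (comma-joined
#'       gene_ids ordered by start).}
#'     \item{membership}{data.frame: `gene_id`, `cluster_id` (`NA` for
#'       non-clustered genes).}
#'   }
#' @export
detect_clusters <- function(mirna_genes, max_gap = 10000L) {
  mg <- mirna_genes[order(mirna_genes$chrom, mirna_genes$strand,
                          mirna_genes$start, mirna_genes$gene_id), ,
                    drop = FALSE]
  membership <- data.frame(gene_id = mirna_genes$gene_id,
                           cluster_id = NA_character_,
                           stringsAsFactors = FALSE)
  clusters <- list()
  k <- 0L
  for (key in unique(paste(mg$chrom, mg$strand))) {
    grp <- mg[paste(mg$chrom, mg$strand) == key, , drop = FALSE]
    if (nrow(grp) < 2L) next
    gap <- grp$start[-1] - grp$end[-nrow(grp)]
    brk <- c(0L, cumsum(gap >= max_gap))
    for (chain in split(seq_len(nrow(grp)), brk)) {
      if (length(chain) < 2L) next
      k <- k + 1L
      cid <- sprintf("cluster_%03d", k)
      members <- grp$gene_id[chain]
      clusters[[k]] <- data.frame(
        cluster_id = cid, chrom = grp$chrom[chain[1]],
        strand = grp$strand[chain[1]],
        start = min(grp$start[chain]), end = max(grp$end[chain]),
        n_members = length(chain),
        members = paste(members, collapse = ","),
        stringsAsFactors = FALSE)
      membership$cluster_id[membership$gene_id %in% members] <- cid
    }
  }
  clusters <- if (length(clusters) > 0L) do.call(rbind, clusters) else
    data.frame(cluster_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer(),
               n_members = integer(), members = character(),
               stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, membership = membership,
                 max_gap = max_gap),
            class = "cluster_set")
}

#' Annotate miRNA genes with location class and cluster membership
#'
#' Convenience wrapper producing the full per-gene context table:
#' [classify_location()] plus [detect_clusters()].
#'
#' @inheritParams classify_location
#' @inheritParams detect_clusters
#' @return the [classify_location()] table with an extra `cluster_id`
#'   column ("" for non-clustered genes); the `cluster_set` is attached as
#'   attribute `"clusters"`.
#' @export
annotate_context <- function(mirna_genes, gene_models, max_gap = 10000L,
                             mirtron_tolerance = 0L) {
  ctx <- classify_location(mirna_genes, gene_models, mirtron_tolerance)
  cs <- detect_clusters(mirna_genes, max_gap)
  cid <- cs$membership$cluster_id[match(ctx$gene_id, cs$membership$gene_id)]
  ctx$cluster_id <- ifelse(is.na(cid), "", cid)
  attr(ctx, "clusters") <- cs
  ctx
}

#' Summarize genomic context per mature miRNA
#'
#' A mature miRNA can be coded at several precursor loci.  Its location
#' classes are the set over all coding loci, and it is flagged clustered if
#' any coding locus belongs to a cluster (so a mature coded in two
#' clusters, as let-7a is, reports both cluster ids).
#'
#' @param matures `matures` data.frame from [read_mirna_gff()].
#' @param context context table from [annotate_context()] (must contain
#'   `cluster_id`).
#' @return data.frame: `mature_id`, `name`, `n_loci`, `gene_ids`,
#'   `location_classes` (comma-joined sorted set), `clustered` (logical),
#'   `cluster_ids`.
#' @export
mature_context <- function(matures, context) {
  if (is.null(context$cluster_id)) {
    stopf("context table lacks cluster_id; use annotate_context()")
  }
  if (nrow(matures) == 0L) {
    return(data.frame(mature_id = character(), name = character(),
                      n_loci = integer(), gene_ids = character(),
                      location_classes = character(), clustered = logical(),
                      cluster_ids = character(), stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(matures)), function(i) {
    gids <- csplit(matures$gene_ids[i])[[1]]
    idx <- match(gids, context$gene_id)
    if (anyNA(idx)) {
      stopf("mature %s references unannotated gene_id(s): %s",
            matures$mature_id[i], paste(gids[is.na(idx)], collapse = ", "))
    }
    cids <- setdiff(unique(context$cluster_id[idx]), "")
    data.frame(
      mature_id = matures$mature_id[i],
      name = matures$name[i],
      n_loci = length(gids),
      gene_ids = paste(gids, collapse = ","),
      location_classes = paste(sort(unique(context$location_class[idx])),
                               collapse = ","),
      clustered = length(cids) > 0L,
      cluster_ids = paste(sort(cids), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
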