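#' Read a miRBase-dialect miRNA GFF3 annotation
#'
#' Parses precursor (`miRNA_primary_transcript`) and mature (`miRNA`)
#' records.  Mature records point at their precursor through the
#' `Derives_from` attribute; resolution is two-pass so child-before-parent
#' files parse.  Mature miRNAs with the same name annotated at several
#' precursor loci (e.g. bta-miR-378 from genes on chromosomes 4 and 7) are
#' merged into a single mature entry carrying all coding `gene_ids`.
#'
#' GFF coordinates are 1-based inclusive; internally everything is 0-based
#' half-open, so a record spanning 1001..1100 becomes `start = 1000`,
#' `end = 1100`.
#'
#' @param path path to a GFF3 file.
#' @return a list with elements
#'   \describe{
#'     \item{genes}{data.frame: `gene_id`, `name`, `chrom`, `start`, `end`,
#'       `strand`, and `mature_ids` (comma-joined).}
#'     \item{matures}{data.frame: `mature_id`, `name`, `sequence` (NA unless
#'       supplied elsewhere) and `gene_ids` (comma-joined).}
#'   }
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   paste("chr1", ".", "miRNA_primary_transcript", "1001", "1100",
#'         ".", "+", ".", "ID=MI1;Name=syn-mir-1", sep = "\t"),
#'   paste("chr1", ".", "miRNA", "1011", "1032", ".", "+", ".",
#'         "ID=MIMAT1;Name=syn-miR-1;Derives_from=MI1", sep = "\t")), gff)
#' read_mirna_gff(gff)$genes
#' @export
read_mirna_gff <- function(path) {
  validate_gff_lines(path, n_fields = 9L)
  empty <- list(
    genes = data.frame(gene_id = character(), name = character(),
                       chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       mature_ids = character(),
                       stringsAsFactors = FALSE),
    matures = data.frame(mature_id = character(), name = character(),
                         sequence = character(), gene_ids = character(),
                         stringsAsFactors = FALSE))
  if (gff_is_empty(path)) return(empty)

  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty)

  is_pre <- df$type == "miRNA_primary_transcript"
  is_mat <- df$type == "miRNA"
  keep <- is_pre | is_mat
  df <- df[keep, , drop = FALSE]
  is_pre <- is_pre[keep]

  bad_strand <- !(as.character(df$strand) %in% c("+", "-"))
  if (any(bad_strand)) {
    stopf("strand is required for miRNA features; missing for: %s",
          paste(df$ID[bad_strand], collapse = ", "))
  }

  genes <- data.frame(
    gene_id = as.character(df$ID[is_pre]),
    name = as.character(df$Name[is_pre] %||% df$ID[is_pre]),
    chrom = as.character(df$seqnames[is_pre]),
    start = to0(df$start[is_pre]),
    end = as.integer(df$end[is_pre]),
    strand = as.character(df$strand[is_pre]),
    stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stopf("duplicate precursor gene_id: %s",
          genes$gene_id[duplicated(genes$gene_id)][1])
  }

  mat <- df[!is_pre, , drop = FALSE]
  if (nrow(mat) > 0L) {
    parent <- as.character(mat$Derives_from)
    unknown <- is.na(parent) | !(parent %in% genes$gene_id)
    if (any(unknown)) {
      stopf("mature record(s) with unknown precursor parent: %s",
            paste(as.character(mat$ID)[unknown], collapse = ", "))
    }
    # merge duplicate mature names across loci into one entry
    mname <- as.character(mat$Name %||% mat$ID)
    split_parents <- split(parent, mname)
    split_ids <- split(as.character(mat$ID), mname)
    nm <- sort(names(split_parents))
    matures <- data.frame(
      mature_id = vapply(split_ids[nm], function(x) sort(x)[1], character(1)),
      name = nm,
      sequence = NA_character_,
      gene_ids = vapply(split_parents[nm],
                        function(x) paste(sort(unique(x)), collapse = ","),
                        character(1)),
      stringsAsFactors = FALSE)
  } else {
    matures <- empty$matures
  }

  # back-link matures onto genes
  g2m <- lapply(genes$gene_id, function(g) {
    matures$mature_id[vapply(csplit(matures$gene_ids),
                             function(p) g %in% p, logical(1))]
  })
  genes$mature_ids <- cjoin(g2m)
  rownames(genes) <- rownames(matures) <- NULL
  list(genes = genes, matures = matures)
}

#' Read protein-coding gene models from GTF or GFF3
#'
#' Gene models are returned flat: a `genes` table and an `exons` table.
#' Exons are sorted by start within each transcript.  For GTF input that
#' carries only `exon` lines, genes and transcripts are reconstructed from
#' the exon spans (gene locus = min/max over its exons).
#'
#' @param path path to the annotation file.
#' @param dialect `"gtf"` or `"gff3"`.
#' @return list with `genes` (gene_id, name, chrom, start, end, strand) and
#'   `exons` (gene_id, transcript_id, chrom, start, end, strand), both in
#'   0-based half-open coordinates.
#' @export
read_gene_models <- function(path, dialect = c("gtf", "gff3")) {
  dialect <- match.arg(dialect)
  validate_gff_lines(path, n_fields = 9L)
  if (gff_is_empty(path)) {
    return(list(
      genes = data.frame(gene_id = character(), name = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         stringsAsFactors = FALSE),
      exons = data.frame(gene_id = character(), transcript_id = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         stringsAsFactors = FALSE)))
  }
  gr <- rtracklayer::import(path, format = dialect)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)

  if (dialect == "gtf") {
    ex <- df[df$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) stopf("no exon features in %s", path)
    if (any(is.na(ex$gene_id)) || any(is.na(ex$transcript_id))) {
      stopf("exon lacking gene_id/transcript_id attribute in %s", path)
    }
    exons <- data.frame(
      gene_id = as.character(ex$gene_id),
      transcript_id = as.character(ex$transcript_id),
      chrom = as.character(ex$seqnames),
      start = to0(ex$start),
      end = as.integer(ex$end),
      strand = as.character(ex$strand),
      stringsAsFactors = FALSE)
    gn <- df[df$type == "gene", , drop = FALSE]
    gene_names <- if (nrow(gn) > 0L && !is.null(gn$gene_name)) {
      stats::setNames(as.character(gn$gene_name), as.character(gn$gene_id))
    } else if (!is.null(ex$gene_name)) {
      stats::setNames(as.character(ex$gene_name), as.character(ex$gene_id))
    } else {
      NULL
    }
  } else {
    ex <- df[df$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) stopf("no exon features in %s", path)
    tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
    parent <- vapply(ex$Parent, function(p) {
      if (length(p) == 0L) NA_character_ else as.character(p)[1]
    }, character(1))
    if (any(is.na(parent))) stopf("exon without transcript Parent in %s", path)
    unknown <- !(parent %in% as.character(tx$ID))
    if (any(unknown)) {
      stopf("exon parent(s) not found as transcript: %s",
            paste(unique(parent[unknown]), collapse = ", "))
    }
    tx_gene <- stats::setNames(
      vapply(tx$Parent, function(p) as.character(p)[1], character(1)),
      as.character(tx$ID))
    exons <- data.frame(
      gene_id = unname(tx_gene[parent]),
      transcript_id = parent,
      chrom = as.character(ex$seqnames),
      start = to0(ex$start),
      end = as.integer(ex$end),
      strand = as.character(ex$strand),
      stringsAsFactors = FALSE)
    gn <- df[df$type == "gene", , drop = FALSE]
    gene_names <- if (nrow(gn) > 0L && !is.null(gn$Name)) {
      stats::setNames(as.character(gn$Name), as.character(gn$ID))
    } else NULL
  }

  if (any(!(exons$strand %in% c("+", "-")))) {
    stopf("strand is required for gene-model features")
  }
  ord <- order(exons$gene_id, exons$transcript_id, exons$start)
  exons <- exons[ord, , drop = FALSE]

  # exons within a transcript must be sorted and non-overlapping
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    s <- exons$start[idx]; e <- exons$end[idx]
    if (length(idx) > 1L && any(s[-1] < e[-length(e)])) {
      stopf("overlapping exons in transcript %s",
            exons$transcript_id[idx[1]])
    }
  }

  agg_start <- tapply(exons$start, exons$gene_id, min)
  agg_end <- tapply(exons$end, exons$gene_id, max)
  gid <- sort(unique(exons$gene_id))
  genes <- data.frame(
    gene_id = gid,
    name = if (is.null(gene_names)) gid else
      ifelse(is.na(gene_names[gid]), gid, gene_names[gid]),
    chrom = exons$chrom[match(gid, exons$gene_id)],
    start = as.integer(agg_start[gid]),
    end = as.integer(agg_end[gid]),
    strand = exons$strand[match(gid, exons$gene_id)],
    stringsAsFactors = FALSE)
  rownames(genes) <- rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

# Cheap structural scan so malformed lines fail with a line number before
# the real parser sees the file.
validate_gff_lines <- function(path, n_fields = 9L) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != n_fields) {
      stopf("malformed line %d in %s: expected %d tab-separated fields, got %d",
            i, path, n_fields, length(f))
    }
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s > e || s < 1L) {
      stopf("malformed line %d in %s: bad coordinates '%s'..'%s'",
            i, path, f[4], f[5])
    }
  }
  invisible(TRUE)
}

gff_is_empty <- function(path) {
  lines <- readLines(path, warn = FALSE)
  !any(nzchar(lines) & !startsWith(lines, "#"))
}
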