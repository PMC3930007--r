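#' Extract the seed region of a mature miRNA
#'
#' The seed is taken as the 7 nucleotides at the 5' end of the mature
#' sequence by default (positions 1-7).  The TargetScan convention
#' (positions 2-8) is available by setting `window_start = 2`.  Input is
#' uppercased and DNA T normalized to RNA U.
#'
#' @param sequence character vector of mature miRNA sequences.
#' @param window_start 1-based position of the first seed nucleotide.
#' @param window_len seed length in nt.
#' @return character vector of seeds.
#' @examples
#' extract_seed("UAUCCCACUUCUGACACCA")        # "UAUCCCA"
#' extract_seed("UAUCCCACUUCUGACACCA", 2, 7)  # "AUCCCAC"
#' @export
extract_seed <- function(sequence, window_start = 1L, window_len = 7L) {
  sequence <- gsub("T", "U", toupper(sequence))
  too_short <- nchar(sequence) < window_start + window_len - 1L
  if (any(too_short)) {
    stopf("sequence(s) shorter than seed window (%d nt needed): %s",
          window_start + window_len - 1L,
          paste(sequence[too_short], collapse = ", "))
  }
  substr(sequence, window_start, window_start + window_len - 1L)
}

#' Group mature miRNAs sharing a seed region
#'
#' miRNAs with different full-length sequences but identical seeds are
#' grouped into a single analysis entry (e.g. miR-1584, miR-2412 and
#' miR-2374 all carry seed UGGGGCU and are treated as one entry).  The
#' entry name is the slash-joined sorted member list.
#'
#' @param names character vector of mature miRNA names.
#' @param seeds character vector of seeds, parallel to `names`.
#' @return data.frame: `seed`, `entry` (slash-joined members), `n_members`.
#' @export
group_by_seed <- function(names, seeds) {
  if (length(names) != length(seeds)) {
    stopf("names and seeds must have equal length")
  }
  if (length(names) == 0L) {
    return(data.frame(seed = character(), entry = character(),
                      n_members = integer(), stringsAsFactors = FALSE))
  }
  sp <- split(names, seeds)
  data.frame(
    seed = names(sp),
    entry = vapply(sp, function(m) paste(sort(m), collapse = "/"),
                   character(1)),
    n_members = vapply(sp, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify seed conservation and species specificity
#'
#' Conservation classes are database labels, copied from a user-supplied
#' TargetScan-style family table, not computed from alignments.  A seed is
#' species-specific when the table records it in no species other than the
#' focal one.  Seeds absent from the table are poorly conserved; since no
#' other species carries them in the supplied table they are treated as
#' focal-species-specific, flagged `in_table = FALSE` so the call can be
#' audited.
#'
#' Species specificity is only asserted for poorly conserved seeds (a seed
#' labeled conserved but listed under one species would be an inconsistent
#' table entry).
#'
#' @param seeds character vector of 7-nt seeds.
#' @param table data.frame from [read_seed_family_table()].
#' @param focal_species species code whose specificity is assessed
#'   (default `"bta"`).
#' @return data.frame: `seed`, `class` (highly_conserved / conserved /
#'   poorly_conserved), `species_specific`, `in_table`.
#' @export
classify_conservation <- function(seeds, table, focal_species = "bta") {
  idx <- match(seeds, table$seed)
  cls <- ifelse(is.na(idx), "poorly_conserved", table$conservation[idx])
  valid <- c("highly_conserved", "conserved", "poorly_conserved")
  if (any(!(cls %in% valid))) {
    stopf("unknown conservation label(s): %s",
          paste(setdiff(unique(cls), valid), collapse = ", "))
  }
  spec <- vapply(seq_along(seeds), function(i) {
    if (is.na(idx[i])) return(TRUE)
    sp <- csplit(table$species[idx[i]])[[1]]
    length(setdiff(sp, focal_species)) == 0L
  }, logical(1))
  spec <- spec & cls == "poorly_conserved"
  data.frame(seed = seeds, class = cls, species_specific = spec,
             in_table = !is.na(idx), stringsAsFactors = FALSE)
}

#' Filter target predictions by total context+ score
#'
#' Keeps records whose total context+ score is at or below the cutoff
#' (score <= -0.3 by default, inclusive) and counts unique predicted
#' target genes per miRNA entry, so two retained sites in one gene count
#' once.
#'
#' @param records data.frame from [read_predictions()].
#' @param cutoff score threshold (default -0.3; more negative = stricter).
#' @return list with `retained` (filtered records) and `counts`
#'   (data.frame `mirna_family`, `n_targets`).
#' @export
filter_predictions <- function(records, cutoff = -0.3) {
  keep <- records$total_context_plus_score <= cutoff
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  fams <- unique(records$mirna_family)
  counts <- data.frame(
    mirna_family = fams,
    n_targets = vapply(fams, function(f) {
      length(unique(retained$gene[retained$mirna_family == f]))
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(retained = retained, counts = counts)
}

#' Tally a table of species-specific miRNAs
#'
#' Summary used for species-specific (e.g. bovine-specific) core miRNA
#' tables: location composition, cluster membership, the largest group of
#' entries sharing one seed, and the ratio of the highest to the lowest
#' mean expression.
#'
#' @param tbl data.frame with columns `mirna`, `clustered` ("yes"/"no" or
#'   logical), `location`, `mean_expression`, `seed`.
#' @return list: `n`, `n_intergenic`, `n_clustered`, `clustered_mirnas`,
#'   `seed_groups` (from [group_by_seed()]), `max_shared_seed_size`,
#'   `expression_fold_range`.
#' @export
summarize_species_specific <- function(tbl) {
  need <- c("mirna", "clustered", "location", "mean_expression", "seed")
  miss <- setdiff(need, colnames(tbl))
  if (length(miss) > 0L) {
    stopf("table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  clustered <- if (is.logical(tbl$clustered)) tbl$clustered else
    tolower(tbl$clustered) %in% c("yes", "true", "1")
  groups <- group_by_seed(tbl$mirna, tbl$seed)
  list(n = nrow(tbl),
       n_intergenic = sum(tbl$location == "intergenic"),
       n_clustered = sum(clustered),
       clustered_mirnas = tbl$mirna[clustered],
       seed_groups = groups,
       max_shared_seed_size = max(groups$n_members),
       expression_fold_range =
         max(tbl$mean_expression) / min(tbl$mean_expression))
}
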