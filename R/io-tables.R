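#' Read an expression intensity matrix with its sample sheet
#'
#' The matrix TSV has miRNA names in the first column and one column per
#' sample; the sample sheet maps every sample column to an individual, a
#' time point and a group label.  Every matrix column must have a sample
#' sheet row; orphans are an error so mislabeled arrays surface early.
#'
#' @param path TSV file, first column miRNA names, remaining columns numeric.
#' @param sample_sheet TSV file with columns `sample_id`, `individual_id`,
#'   `time_point`, `group`.
#' @return list with `matrix` (numeric, rownames = miRNAs, colnames =
#'   sample_ids) and `samples` (the sample sheet data.frame).
#' @export
read_expression <- function(path, sample_sheet) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stopf("expression matrix needs >= 1 sample column")
  ids <- as.character(raw[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stopf("duplicated miRNA row name(s): %s",
          paste(unique(dup), collapse = ", "))
  }
  body <- raw[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad) > 0L) {
        stopf("non-numeric value '%s' at row %d (%s), column '%s'",
              v[bad[1]], bad[1], ids[bad[1]], colnames(body)[j])
      }
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids

  samples <- read_sample_sheet(sample_sheet)
  orphan <- setdiff(colnames(mat), samples$sample_id)
  if (length(orphan) > 0L) {
    stopf("matrix column(s) missing from sample sheet: %s",
          paste(orphan, collapse = ", "))
  }
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  list(matrix = mat, samples = samples)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `individual_id`, `time_point`,
#'   `group`.
#' @return data.frame with those columns; sample_ids are checked unique.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "time_point", "group")
  miss <- setdiff(need, colnames(ss))
  if (length(miss) > 0L) {
    stopf("sample sheet lacks column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ss$sample_id)) {
    stopf("duplicated sample_id(s): %s",
          paste(unique(ss$sample_id[duplicated(ss$sample_id)]),
                collapse = ", "))
  }
  ss[, need, drop = FALSE]
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `sample_id`, `assay`, `replicate`, `ct`.
#' @return validated data.frame; Ct values must be finite and positive.
#' @export
read_qpcr <- function(path) {
  q <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay", "replicate", "ct")
  miss <- setdiff(need, colnames(q))
  if (length(miss) > 0L) {
    stopf("qPCR table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  if (!is.numeric(q$ct) || any(!is.finite(q$ct)) || any(q$ct <= 0)) {
    stopf("Ct values must be finite and > 0")
  }
  q[, need, drop = FALSE]
}

#' Read a TargetScan-style seed family table
#'
#' One row per miRNA family: the 7-nt seed, the family name, the
#' semicolon/comma-separated set of species codes in which the seed occurs,
#' and the database conservation label.
#'
#' @param path TSV with columns `seed`, `family`, `species`, `conservation`.
#' @param seed_len expected seed length (default 7).
#' @return data.frame with `species` normalized to comma-joined codes.
#' @export
read_seed_family_table <- function(path, seed_len = 7L) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seed", "family", "species", "conservation")
  miss <- setdiff(need, colnames(tb))
  if (length(miss) > 0L) {
    stopf("seed family table lacks column(s): %s",
          paste(miss, collapse = ", "))
  }
  tb$seed <- gsub("T", "U", toupper(tb$seed))
  bad <- nchar(tb$seed) != seed_len | grepl("[^ACGU]", tb$seed)
  if (any(bad)) {
    stopf("invalid seed(s): %s", paste(tb$seed[bad], collapse = ", "))
  }
  tb$species <- gsub("[;[:space:]]+", ",", tb$species)
  tb[, need, drop = FALSE]
}

#' Read target-prediction records with context+ scores
#'
#' @param path TSV with columns `mirna_family`, `gene`,
#'   `total_context_plus_score`.
#' @return validated data.frame.
#' @export
read_predictions <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_family", "gene", "total_context_plus_score")
  miss <- setdiff(need, colnames(p))
  if (length(miss) > 0L) {
    stopf("prediction table lacks column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (any(!is.finite(p$total_context_plus_score))) {
    stopf("non-finite context+ score(s)")
  }
  p[, need, drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' Thin wrapper around [fgsea::gmtPathways()].
#'
#' @param path GMT file (term, description, tab-separated genes).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read mature miRNA sequences from FASTA
#'
#' Sequences are uppercased and DNA T is normalized to RNA U.
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return named character vector (names = first word of each header).
#' @export
read_mature_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  stats::setNames(gsub("T", "U", toupper(as.character(ss))), nm)
}
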