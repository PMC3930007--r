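#' Aggregate qPCR technical replicates
#'
#' Arithmetic mean Ct per (sample, assay) with the replicate SD alongside;
#' triples whose SD exceeds `sd_limit` are flagged as outlier reactions.
#' (Sample, assay) combinations expected but absent are listed in a gap
#' report rather than raised as an error, so partially failed plates can
#' still be analysed.
#'
#' @param qpcr data.frame from [read_qpcr()].
#' @param sd_limit replicate-SD flag threshold in cycles (default 0.5).
#' @param expected optional data.frame (`sample_id`, `assay`) of reactions
#'   that should be present.
#' @return list: `ct` (data.frame `sample_id`, `assay`, `ct_mean`,
#'   `ct_sd`, `n_replicates`, `flagged`) and `gaps` (missing reactions).
#' @export
aggregate_replicates <- function(qpcr, sd_limit = 0.5, expected = NULL) {
  key <- interaction(qpcr$sample_id, qpcr$assay, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(qpcr, key), function(d) {
    data.frame(sample_id = d$sample_id[1], assay = d$assay[1],
               ct_mean = mean(d$ct),
               ct_sd = if (nrow(d) > 1L) stats::sd(d$ct) else NA_real_,
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg$flagged <- !is.na(agg$ct_sd) & agg$ct_sd > sd_limit |
    agg$n_replicates == 1L
  gaps <- if (is.null(expected)) {
    data.frame(sample_id = character(), assay = character(),
               stringsAsFactors = FALSE)
  } else {
    have <- paste(agg$sample_id, agg$assay)
    miss <- !(paste(expected$sample_id, expected$assay) %in% have)
    expected[miss, c("sample_id", "assay"), drop = FALSE]
  }
  rownames(gaps) <- NULL
  list(ct = agg, gaps = gaps)
}

#' Delta-Ct relative to a reference assay
#'
#' `delta_ct = ct_target - ct_reference` (per sample); lower Ct means
#' higher expression, so larger delta-Ct means lower expression relative
#' to the reference.
#'
#' @param ct_target,ct_reference numeric Ct values (vectorized).
#' @return numeric delta-Ct.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(is.na(ct_target)) || any(is.na(ct_reference))) {
    stopf("missing Ct value(s) in delta-Ct computation")
  }
  ct_target - ct_reference
}

#' Delta-delta-Ct fold change
#'
#' `ddct = delta_ct_sample - delta_ct_calibrator`; fold change =
#' `2^(-ddct)` (relative quantification).
#'
#' @param delta_ct_sample,delta_ct_calibrator numeric delta-Ct values.
#' @return numeric fold changes.
#' @export
ddct_fold <- function(delta_ct_sample, delta_ct_calibrator) {
  2^(-(delta_ct_sample - delta_ct_calibrator))
}

#' Two-tailed p-value for a Pearson correlation coefficient
#'
#' Uses the t transform `t = R * sqrt(n - 2) / sqrt(1 - R^2)` with n - 2
#' degrees of freedom (the test behind [stats::cor.test()]), so printed
#' correlation tables can be re-checked from R and n alone.
#'
#' @param r Pearson correlation coefficient(s).
#' @param n number of paired observations.
#' @return two-tailed p-value(s).
#' @examples
#' pearson_pvalue(0.624, 12)  # 0.030
#' @export
pearson_pvalue <- function(r, n) {
  if (any(n < 3L)) stopf("need n >= 3")
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Correlate two expression profiles
#'
#' Pearson correlation with the two-tailed t-transform p-value; incomplete
#' pairs are dropped listwise.
#'
#' @param x,y numeric vectors (per-sample expression), matched by
#'   position.
#' @return list of class `correlation_result`: `n`, `r`, `p`.
#' @export
correlate_pair <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need >= 3 complete pairs")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(n = length(x), r = unname(ct$estimate),
                 p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson R = %.3f, n = %d, two-tailed p = %.4g\n",
              x$r, x$n, x$p))
  invisible(x)
}

#' Host-gene vs intronic-miRNA co-expression from qPCR
#'
#' For each (gene, miRNA) pair, per-sample expression is taken as
#' `-delta_ct` (target Ct minus the matching reference assay Ct, sign
#' flipped so that higher values mean higher expression and a positive R
#' means co-expression), and the two profiles are correlated with
#' [correlate_pair()].  Genes are referenced against `gene_ref`
#' (beta-actin by default) and miRNAs against `mirna_ref` (miR-181a by
#' default), mirroring common qPCR reference choices in adipose studies.
#'
#' @param ct aggregated Ct table from [aggregate_replicates()] (`$ct`).
#' @param pairs data.frame with columns `gene`, `mirna` (assay names).
#' @param mirna_ref reference assay for miRNAs.
#' @param gene_ref reference assay for genes.
#' @return data.frame: `gene`, `mirna`, `n`, `r`, `p`.
#' @export
qpcr_host_correlation <- function(ct, pairs, mirna_ref = "bta-miR-181a",
                                  gene_ref = "ACTB") {
  get_assay <- function(assay) {
    d <- ct[ct$assay == assay, , drop = FALSE]
    stats::setNames(d$ct_mean, d$sample_id)
  }
  ref_g <- get_assay(gene_ref)
  ref_m <- get_assay(mirna_ref)
  if (length(ref_g) == 0L) stopf("gene reference assay '%s' absent", gene_ref)
  if (length(ref_m) == 0L) stopf("miRNA reference assay '%s' absent",
                                 mirna_ref)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- get_assay(pairs$gene[i])
    m <- get_assay(pairs$mirna[i])
    samp <- Reduce(intersect, list(names(g), names(m), names(ref_g),
                                   names(ref_m)))
    expr_g <- -delta_ct(g[samp], ref_g[samp])
    expr_m <- -delta_ct(m[samp], ref_m[samp])
    cr <- correlate_pair(expr_g, expr_m)
    data.frame(gene = pairs$gene[i], mirna = pairs$mirna[i], n = cr$n,
               r = cr$r, p = cr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
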