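#' Right-tailed Fisher's exact test for gene-set overlap
#'
#' Probability of observing an overlap at least as large as `k` when `n`
#' query genes are drawn from a universe of `N` genes of which `m` belong
#' to the set: `p = P(X >= k)` under Hypergeometric(N, m, n).
#'
#' @param k overlap count (query genes in the set).
#' @param n query size.
#' @param m set size (within the universe).
#' @param N universe size.
#' @return right-tail probability.
#' @examples
#' fisher_right(10, 10, 10, 20)  # 1 / choose(20, 10)
#' fisher_right(0, 10, 10, 20)   # 1
#' @export
fisher_right <- function(k, n, m, N) {
  if (any(k < 0 | n < 0 | m < 0 | N < 0) ||
      any(k > n) || any(k > m) || any(n > N) || any(m > N)) {
    stopf("inconsistent counts: need 0 <= k <= min(n, m) and n, m <= N")
  }
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Gene-set enrichment of a query list (right-tailed Fisher)
#'
#' Each gene set is intersected with the universe and tested for
#' over-representation in the query with [fisher_right()].  Gene symbols
#' are matched case-insensitively and exactly (no alias resolution).
#' Query genes outside the universe are dropped with a warning.  Results
#' are sorted by ascending p; `-log10(p)` is reported for plotting, and
#' significance is flagged at `alpha` on raw p-values by default or on
#' Benjamini-Hochberg adjusted values with `bh = TRUE`.
#'
#' @param query character vector of query gene symbols.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of all assayable gene symbols.
#' @param alpha significance level (default 0.05).
#' @param bh apply Benjamini-Hochberg correction before flagging.
#' @return data.frame: `term`, `k`, `n`, `m`, `N`, `p`, `p_adj`,
#'   `neglog10p`, `significant`, `genes` (comma-joined overlap).
#' @export
enrich <- function(query, gene_sets, universe, alpha = 0.05, bh = FALSE) {
  if (length(universe) == 0L) stopf("empty universe")
  uni <- unique(toupper(universe))
  q <- unique(toupper(query))
  outside <- setdiff(q, uni)
  if (length(outside) > 0L) {
    warnf("query gene(s) outside universe dropped: %s",
          paste(outside, collapse = ", "))
    q <- intersect(q, uni)
  }
  res <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(toupper(gene_sets[[term]])), uni)
    hits <- sort(intersect(q, set))
    data.frame(term = term, k = length(hits), n = length(q),
               m = length(set), N = length(uni),
               p = fisher_right(length(hits), length(q), length(set),
                                length(uni)),
               genes = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$neglog10p <- -log10(out$p)
  out$significant <- (if (bh) out$p_adj else out$p) < alpha
  out <- out[order(out$p, out$term),
             c("term", "k", "n", "m", "N", "p", "p_adj", "neglog10p",
               "significant", "genes")]
  rownames(out) <- NULL
  out
}
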