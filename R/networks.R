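#' Pairwise Pearson correlation matrix of miRNA expression
#'
#' Correlations are computed between miRNA rows across samples (pairwise
#' complete observations).  Rows with zero variance carry no correlation
#' information and are excluded with a warning naming them.
#'
#' @param mat normalized matrix (miRNAs x samples), >= 3 samples.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(mat) {
  if (ncol(mat) < 3L) stopf("need >= 3 samples for correlations")
  v <- apply(mat, 1, stats::var, na.rm = TRUE)
  zero <- !is.finite(v) | v == 0
  if (any(zero)) {
    warnf("excluding zero-variance row(s): %s",
          paste(rownames(mat)[zero], collapse = ", "))
    mat <- mat[!zero, , drop = FALSE]
  }
  r <- stats::cor(t(mat), use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Build a relevance network from a correlation matrix
#'
#' Edges connect miRNA pairs whose squared Pearson correlation reaches the
#' threshold (`R^2 >= r2_threshold`, inclusive); the sign of R is kept, so
#' strong negative co-expression also forms an edge.  The "networks" are
#' the connected components of the edge graph (size >= 2), ordered by
#' decreasing size and then lexicographically by first member; nodes
#' without any edge are not part of a network.
#'
#' @param r symmetric correlation matrix (from [correlation_matrix()]).
#' @param r2_threshold squared-correlation threshold (default 0.95).
#' @return object of class `relevance_network`: list with `nodes` (all
#'   matrix rows), `edges` (data.frame `node_a`, `node_b`, `r`, `sign`),
#'   `components` (list of sorted member vectors) and `threshold`.
#' @export
build_network <- function(r, r2_threshold = 0.95) {
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8))) {
    stopf("correlation matrix must be symmetric")
  }
  nodes <- rownames(r) %||% as.character(seq_len(nrow(r)))
  idx <- which(upper.tri(r) & r^2 >= r2_threshold, arr.ind = TRUE)
  edges <- data.frame(
    node_a = nodes[idx[, 1]],
    node_b = nodes[idx[, 2]],
    r = r[idx],
    sign = ifelse(r[idx] >= 0, "+", "-"),
    stringsAsFactors = FALSE)
  swap <- edges$node_a > edges$node_b
  tmp <- edges$node_a[swap]
  edges$node_a[swap] <- edges$node_b[swap]
  edges$node_b[swap] <- tmp
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL

  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    members <- split(names(comp$membership), comp$membership)
    members <- lapply(members, function(m) sort(m))
    ord <- order(-vapply(members, length, integer(1)),
                 vapply(members, function(m) m[1], character(1)))
    components <- unname(members[ord])
  } else {
    components <- list()
  }
  structure(list(nodes = nodes, edges = edges, components = components,
                 threshold = r2_threshold),
            class = "relevance_network")
}

#' @export
print.relevance_network <- function(x, ...) {
  cat(sprintf("Relevance network (R2 >= %g): %d nodes, %d edges, %d %s\n",
              x$threshold, length(x$nodes), nrow(x$edges),
              length(x$components), "component(s)"))
  for (i in seq_along(x$components)) {
    cat(sprintf("  network %d (n = %d): %s\n", i,
                length(x$components[[i]]),
                paste(x$components[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Annotate network components with context and conservation
#'
#' Per component: size, conservation composition, how many members have a
#' clustered coding locus and which genomic cluster ids are represented.
#' Members missing from the attribute tables are counted as `unknown`.
#'
#' @param network `relevance_network` from [build_network()].
#' @param mature_ctx optional data.frame from [mature_context()] (matched
#'   on `name`).
#' @param conservation optional data.frame with columns `name`, `class`.
#' @return data.frame: `component`, `size`, `members`, conservation
#'   counts and `pct_highly_conserved`, `n_clustered`, `cluster_ids`.
#' @export
annotate_components <- function(network, mature_ctx = NULL,
                                conservation = NULL) {
  comps <- network$components
  if (length(comps) == 0L) {
    return(data.frame(component = integer(), size = integer(),
                      members = character(), n_highly_conserved = integer(),
                      n_conserved = integer(), n_poorly_conserved = integer(),
                      n_unknown = integer(), pct_highly_conserved = numeric(),
                      n_clustered = integer(), cluster_ids = character(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(seq_along(comps), function(i) {
    m <- comps[[i]]
    cls <- if (is.null(conservation)) rep("unknown", length(m)) else {
      cc <- conservation$class[match(m, conservation$name)]
      ifelse(is.na(cc), "unknown", cc)
    }
    if (is.null(mature_ctx)) {
      nclust <- NA_integer_; cids <- ""
    } else {
      j <- match(m, mature_ctx$name)
      nclust <- sum(mature_ctx$clustered[j], na.rm = TRUE)
      cids <- paste(sort(unique(unlist(csplit(
        mature_ctx$cluster_ids[j[!is.na(j)]])))), collapse = ",")
    }
    data.frame(component = i, size = length(m),
               members = paste(m, collapse = ","),
               n_highly_conserved = sum(cls == "highly_conserved"),
               n_conserved = sum(cls == "conserved"),
               n_poorly_conserved = sum(cls == "poorly_conserved"),
               n_unknown = sum(cls == "unknown"),
               pct_highly_conserved =
                 100 * sum(cls == "highly_conserved") / length(m),
               n_clustered = nclust, cluster_ids = cids,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
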