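#' Write a pipeline result to disk
#'
#' Tabular results (context tables, cluster tables, edge lists, summary
#' statistics, enrichment tables) are written as TSV; structured results
#' (power fits, relevance networks) can also be written as JSON.  Written
#' TSVs round-trip: reading them back reproduces the in-memory object.
#'
#' @param x a data.frame, a `power_fit` or a `relevance_network`.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("directory does not exist: %s", dir)
  if (format == "json") {
    obj <- if (inherits(x, "power_fit")) {
      list(a = x$a, b = x$b, r2 = x$r2, n_points = x$n_points,
           pearson_r = x$pearson_r)
    } else if (inherits(x, "relevance_network")) {
      list(threshold = x$threshold, edges = x$edges,
           components = x$components)
    } else {
      x
    }
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    df <- if (inherits(x, "relevance_network")) x$edges else as.data.frame(x)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back a written network edge list
#'
#' @param path TSV written by [write_outputs()] from a `relevance_network`.
#' @return data.frame with columns `node_a`, `node_b`, `r`, `sign`.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read back a written context table
#'
#' @param path TSV written by [write_outputs()] from a context annotation
#'   table.
#' @return data.frame matching the in-memory context table.
#' @export
read_context_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA"))
  for (col in c("host_gene_ids", "host_orientation", "cluster_id")) {
    if (col %in% colnames(df)) {
      df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
    }
  }
  df
}
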