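# Internal helpers shared across modules.

# Internal coordinates are 0-based half-open (BED-style): a feature printed
# as 1-based inclusive [s, e] in GFF/GTF becomes [s - 1, e).  Lengths are
# then end - start everywhere, and round-tripping back to GFF is start + 1.
to0 <- function(start1) as.integer(start1) - 1L

from0 <- function(start0) as.integer(start0) + 1L

#' Width of an interval in internal coordinates
#' @param start,end 0-based half-open bounds
#' @return integer widths
#' @keywords internal
interval_width <- function(start, end) as.integer(end) - as.integer(start)

# a strictly inside b (no shared bounds required, containment inclusive)
contained_in <- function(a_start, a_end, b_start, b_end) {
  a_start >= b_start & a_end <= b_end
}

overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & a_end > b_start
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# comma-join a character vector for flat TSV columns ("" for empty)
cjoin <- function(x) {
  vapply(x, function(v) paste(v, collapse = ","), character(1))
}

csplit <- function(x) {
  lapply(x, function(v) if (is.na(v) || !nzchar(v)) character(0)
         else strsplit(v, ",", fixed = TRUE)[[1]])
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
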