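#' Percentile-shift normalization of intensity data
#'
#' Per-sample scaling in the style of array percentile normalization:
#' each value is log-transformed and shifted so the chosen percentile of
#' the sample's log intensities equals `offset` (0 by default),
#' i.e. `v -> log2(v) - P75(log2 v of that sample) + offset`.  Percentiles
#' use linear interpolation between order statistics (quantile type 7).
#' Non-positive raw values cannot be log-transformed and are masked to
#' `NA` (arrays report such values for undetected probes).
#'
#' Normalizing an already-normalized matrix on the linear scale is a no-op
#' because the transform is invariant to per-sample multiplicative
#' factors.
#'
#' @param raw numeric matrix, miRNAs x samples, raw intensities.
#' @param percentile percentile to pin, in (0, 100] (default 75).
#' @param log_base logarithm base (default 2).
#' @param offset value the pinned percentile maps to (default 0).
#' @return numeric matrix of normalized log intensities with attributes
#'   `percentile`, `log_base`, `offset`.
#' @export
normalize_percentile <- function(raw, percentile = 75, log_base = 2,
                                 offset = 0) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  lg <- raw
  lg[!is.na(lg) & lg <= 0] <- NA
  lg <- log(lg, base = log_base)
  out <- lg
  for (j in seq_len(ncol(lg))) {
    v <- lg[, j]
    if (all(is.na(v))) {
      stopf("sample '%s' has no positive intensities to normalize",
            colnames(lg)[j] %||% as.character(j))
    }
    p <- stats::quantile(v, probs = percentile / 100, na.rm = TRUE,
                         type = 7, names = FALSE)
    out[, j] <- v - p + offset
  }
  attr(out, "percentile") <- percentile
  attr(out, "log_base") <- log_base
  attr(out, "offset") <- offset
  out
}

#' Detect the tissue core miRNA set
#'
#' A miRNA belongs to the core set when it is detected in every individual
#' in at least one time point.  Two readings of that rule are available:
#' \describe{
#'   \item{`per-individual`}{(default) each individual must have >= 1
#'     sample in which the miRNA is detected, time points may differ
#'     between individuals;}
#'   \item{`common-timepoint`}{there must exist one time point at which
#'     the miRNA is detected in all individuals.}
#' }
#' Detection is either an explicit logical flag matrix (such as array
#' feature-extraction presence calls) or a threshold on the normalized
#' value: detected when the value is non-missing and strictly greater
#' than `floor`.  The default floor is the matrix minimum, treating the
#' lowest observed value as the undetected baseline.
#'
#' @param mat normalized matrix from [normalize_percentile()].
#' @param samples sample sheet data.frame (columns `sample_id`,
#'   `individual_id`, `time_point`).
#' @param flags optional logical matrix, same shape as `mat`.
#' @param floor detection floor on the normalized scale (ignored when
#'   `flags` is given).
#' @param rule `"per-individual"` or `"common-timepoint"`.
#' @return list: `core` (character vector of core miRNA names), `detected`
#'   (logical matrix), `rule`, `floor`.
#' @export
detect_core <- function(mat, samples, flags = NULL, floor = NULL,
                        rule = c("per-individual", "common-timepoint")) {
  rule <- match.arg(rule)
  miss <- setdiff(colnames(mat), samples$sample_id)
  if (length(miss) > 0L) {
    stopf("samples missing from sheet: %s", paste(miss, collapse = ", "))
  }
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  if (any(table(samples$individual_id) == 0L)) {
    stopf("individual with zero samples")
  }
  if (is.null(flags)) {
    if (is.null(floor)) floor <- min(mat, na.rm = TRUE)
    detected <- !is.na(mat) & mat > floor
  } else {
    if (!identical(dim(flags), dim(mat))) {
      stopf("flag matrix dimensions do not match the expression matrix")
    }
    detected <- flags & !is.na(flags)
    floor <- NA_real_
  }

  indiv <- unique(samples$individual_id)
  if (rule == "per-individual") {
    per_ind <- vapply(indiv, function(id) {
      cols <- samples$sample_id[samples$individual_id == id]
      rowSums(detected[, cols, drop = FALSE]) > 0L
    }, logical(nrow(mat)))
    core <- rownames(mat)[rowSums(per_ind) == length(indiv)]
  } else {
    tps <- unique(samples$time_point)
    per_tp <- vapply(tps, function(tp) {
      cols <- samples$sample_id[samples$time_point == tp]
      ids <- samples$individual_id[samples$time_point == tp]
      if (length(unique(ids)) < length(indiv)) {
        return(rep(FALSE, nrow(mat)))
      }
      rowSums(detected[, cols, drop = FALSE]) == length(cols)
    }, logical(nrow(mat)))
    core <- rownames(mat)[rowSums(per_tp) > 0L]
  }
  list(core = core, detected = detected, rule = rule, floor = floor)
}

#' Per-miRNA summary statistics (mean, SD, CV)
#'
#' Computes each miRNA's mean, sample standard deviation (n - 1) and
#' coefficient of variation (CV = sd / mean) across all samples.  By
#' default statistics are taken on the back-transformed linear scale
#' (`2^normalized`, intensity relative to the pinned percentile), which
#' keeps means positive and makes the CV the conventional relative
#' variability; `scale = "log"` uses the matrix values as-is.  Rows with
#' non-positive mean have an undefined CV and are flagged.
#'
#' @param mat normalized matrix (miRNAs x samples).
#' @param scale `"linear"` (back-transform by `log_base^value`) or
#'   `"log"`.
#' @return data.frame: `mirna`, `mean`, `sd`, `cv`, `n_samples`,
#'   `flagged`.
#' @export
summarize_expression <- function(mat, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (ncol(mat) < 2L) stopf("need >= 2 samples to summarize")
  x <- if (scale == "linear") {
    (attr(mat, "log_base") %||% 2)^mat
  } else {
    mat
  }
  m <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1, stats::sd, na.rm = TRUE)
  n <- rowSums(!is.na(x))
  flagged <- m <= 0
  cv <- ifelse(flagged, NA_real_, s / m)
  data.frame(mirna = rownames(mat) %||% as.character(seq_along(m)),
             mean = unname(m), sd = unname(s), cv = unname(cv),
             n_samples = unname(n), flagged = unname(flagged),
             stringsAsFactors = FALSE)
}

#' Fit the power-law relation between expression and variability
#'
#' Fits `mean = a * CV^b` by ordinary least squares of `log(mean)` on
#' `log(CV)` using points with positive mean and CV; `a` is the
#' back-transformed intercept, `b` the slope and `r2` the coefficient of
#' determination of the log-log regression.  The Pearson correlation of
#' mean and CV on the untransformed scale is returned alongside.
#'
#' @param stats data.frame from [summarize_expression()] (columns `mean`,
#'   `cv`).
#' @return object of class `power_fit`: list `a`, `b`, `r2`, `n_points`,
#'   `pearson_r`.
#' @export
fit_power <- function(stats) {
  ok <- is.finite(stats$mean) & is.finite(stats$cv) &
    stats$mean > 0 & stats$cv > 0
  if (sum(ok) < 3L) stopf("need >= 3 usable points for the power fit")
  lx <- log(stats$cv[ok]); ly <- log(stats$mean[ok])
  fit <- stats::lm(ly ~ lx)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r2 = r2,
                 n_points = sum(ok),
                 pearson_r = if (stats::sd(stats$mean[ok]) == 0 ||
                                 stats::sd(stats$cv[ok]) == 0) NA_real_
                             else stats::cor(stats$mean[ok], stats$cv[ok])),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("Power fit: y = %.4f * x^%.4f  (R2 = %.3f, n = %d)\n",
              x$a, x$b, x$r2, x$n_points))
  cat(sprintf("Pearson R (mean vs CV, untransformed): %.3f\n", x$pearson_r))
  invisible(x)
}

#' Compare a per-miRNA statistic between categories
#'
#' With two groups, a two-tailed pooled-variance t-test (Welch by
#' setting `var_equal = FALSE`); with three or more, a one-way ANOVA
#' followed by Tukey's HSD at `alpha`.
#'
#' @param values numeric vector (e.g. mean expression or target counts).
#' @param labels category label per value.
#' @param var_equal pool variances in the two-group t-test (default TRUE).
#' @param alpha familywise level for Tukey significance flags.
#' @return object of class `category_comparison`: list with `groups`
#'   (n/mean/sd per group), `test` ("t" or "anova"), `statistic`, `p`,
#'   and for >= 3 groups `tukey` (difference, adjusted p, significant).
#' @export
compare_categories <- function(values, labels, var_equal = TRUE,
                               alpha = 0.05) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  ng <- table(labels)
  if (length(ng) < 2L) stopf("need >= 2 groups")
  if (any(ng < 2L)) {
    stopf("group(s) with n < 2: %s",
          paste(names(ng)[ng < 2L], collapse = ", "))
  }
  groups <- data.frame(
    group = names(ng),
    n = as.integer(ng),
    mean = as.numeric(tapply(values, labels, mean)[names(ng)]),
    sd = as.numeric(tapply(values, labels, stats::sd)[names(ng)]),
    stringsAsFactors = FALSE)

  if (length(ng) == 2L) {
    tt <- stats::t.test(values[labels == names(ng)[1]],
                        values[labels == names(ng)[2]],
                        var.equal = var_equal)
    out <- list(groups = groups, test = "t",
                statistic = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter), tukey = NULL)
  } else {
    f <- factor(labels)
    av <- stats::aov(values ~ f)
    sm <- summary(av)[[1]]
    tk <- stats::TukeyHSD(av, conf.level = 1 - alpha)$f
    tukey <- data.frame(
      comparison = rownames(tk),
      difference = tk[, "diff"],
      p_adj = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha,
      row.names = NULL, stringsAsFactors = FALSE)
    out <- list(groups = groups, test = "anova",
                statistic = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
                df = c(sm[["Df"]][1], sm[["Df"]][2]), tukey = tukey)
  }
  class(out) <- "category_comparison"
  out
}

#' @export
print.category_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g\n",
              if (x$test == "t") "Two-tailed t-test" else "One-way ANOVA",
              x$statistic, x$p))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$tukey)) {
    cat("Tukey HSD:\n")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}
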