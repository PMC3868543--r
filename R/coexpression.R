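# Template-matching co-expression and fold-change rankings.

#' Pavlidis template matching: expression neighbors of a template gene
#'
#' Correlates every gene's expression profile with the template gene's
#' profile (Pearson) and converts r to a two-sided p-value via
#' `t = r * sqrt(n-2) / sqrt(1-r^2)` on `n-2` degrees of freedom.  Genes at
#' or below the p-value threshold are returned, the template itself
#' excluded.
#'
#' @param x A `norm_matrix` (or `count_matrix`).
#' @param template_gene Gene id present in the matrix.
#' @param p_threshold Significance cutoff (default 1e-5).
#' @return Data frame `gene_id`, `pearson_r`, `p_value`, `n_samples`,
#'   sorted by p-value.
#' @export
ptm_neighbors <- function(x, template_gene, p_threshold = 1e-5) {
  nm <- as_norm_matrix(x)
  v <- nm$values
  if (!template_gene %in% rownames(v))
    abort("template gene absent", "annotation_error")
  n <- ncol(v)
  if (n < 4) abort("need at least 4 samples", "statistics_error")
  tpl <- v[template_gene, ]
  if (sd(tpl) == 0) abort("zero-variance template", "statistics_error")
  keep <- apply(v, 1, sd) > 0
  r <- as.vector(cor(t(v[keep, , drop = FALSE]), tpl))
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- data.frame(gene_id = rownames(v)[keep], pearson_r = r, p_value = p,
                    n_samples = n, stringsAsFactors = FALSE)
  out <- out[out$gene_id != template_gene & out$p_value <= p_threshold, ,
             drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

#' Whole-genome ranking by group log fold change
#'
#' Ranks all genes by mean log2 difference between samples "expressing" a
#' marker gene and the remaining samples.  A sample expresses the marker
#' when its normalized value exceeds the cohort 75th percentile of that
#' gene; alternatively an explicit logical grouping can be given.
#'
#' @param x A `norm_matrix` (or `count_matrix`).
#' @param marker_gene Gene id defining the expressing group, or `NULL`.
#' @param sample_groups Logical vector (TRUE = expressing) overriding the
#'   marker rule.
#' @return Named numeric vector of log2 fold changes, descending.
#' @export
rank_by_group_lfc <- function(x, marker_gene = NULL, sample_groups = NULL) {
  nm <- as_norm_matrix(x)
  v <- nm$values
  if (is.null(sample_groups)) {
    if (is.null(marker_gene) || !marker_gene %in% rownames(v))
      abort("marker gene absent", "annotation_error")
    expr <- v[marker_gene, ]
    sample_groups <- expr > quantile(expr, 0.75, names = FALSE)
  }
  if (!any(sample_groups) || all(sample_groups))
    abort("marker expressed in all or no samples", "grouping_error")
  lfc <- rowMeans(v[, sample_groups, drop = FALSE]) -
    rowMeans(v[, !sample_groups, drop = FALSE])
  sort(lfc, decreasing = TRUE)
}
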