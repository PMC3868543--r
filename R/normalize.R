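# Expression normalization: within-sample covariate (GC/length) trend
# removal, between-sample scaling, linear batch-effect removal, MDS
# diagnostics, TF-based subtype clustering.  All steps operate on the
# log2(count + 0.5) scale and record provenance.

#' Convert a count matrix to the log2 normalized container
#'
#' @param x A `count_matrix` from [simulate_counts()] or an integer matrix.
#' @param gene_annot,sample_meta Annotations (taken from `x` when it is a
#'   `count_matrix`).
#' @param offset Pseudo-count added before log2 (default 0.5).
#' @return A `norm_matrix`: list with `values` (log2 matrix), `gene_annot`,
#'   `sample_meta`, `provenance` (character vector of applied steps).
#' @export
as_norm_matrix <- function(x, gene_annot = NULL, sample_meta = NULL,
                           offset = 0.5) {
  if (inherits(x, "norm_matrix")) return(x)
  if (inherits(x, "count_matrix")) {
    gene_annot <- x$gene_annot; sample_meta <- x$sample_meta
    x <- x$counts
  }
  if (any(x < 0)) abort("negative counts", "format_error")
  structure(list(values = log2(x + offset), gene_annot = gene_annot,
                 sample_meta = sample_meta,
                 provenance = sprintf("log2(count + %g)", offset)),
            class = "norm_matrix")
}

#' Within-sample covariate normalization (GC or length)
#'
#' Per sample, a lowess trend of log2 expression on the covariate is
#' estimated and subtracted, preserving the sample mean.  Removes the
#' smooth GC-content or gene-length bias so per-gene means are comparable
#' across the covariate range.
#'
#' The trend is only subtracted when the covariate carries signal: a
#' per-sample quadratic F-test gates the correction (default alpha 1e-4),
#' so a bias-free sample passes through unchanged instead of absorbing
#' smoother noise from the gene-level expression spread.
#'
#' @param x A `count_matrix` or `norm_matrix` (gene annotation required).
#' @param covariate `"gc"` or `"length"`.
#' @param span Lowess smoother span (default 0.4; with thousands of genes
#'   the fit averages over far more than 10 effective covariate bins).
#' @param gate_alpha Significance level of the per-sample quadratic
#'   trend test below which the correction is applied (default 1e-4).
#' @return A `norm_matrix` with the trend removed.
#' @export
within_sample_normalize <- function(x, covariate = c("gc", "length"),
                                    span = 0.4, gate_alpha = 1e-4) {
  covariate <- match.arg(covariate)
  nm <- as_norm_matrix(x)
  if (is.null(nm$gene_annot))
    abort("gene annotation required for covariate normalization",
          "format_error")
  cov <- switch(covariate, gc = nm$gene_annot$gc,
                length = log2(nm$gene_annot$exonic_length))
  if (length(unique(cov)) == 1) {
    warning("constant covariate: nothing to normalize")
    return(nm)
  }
  v <- nm$values
  o <- order(cov)
  X <- stats::poly(cov, 2)
  for (j in seq_len(ncol(v))) {
    fit2 <- stats::lm(v[, j] ~ X)
    pf <- stats::pf(summary(fit2)$fstatistic[1], 2, length(cov) - 3,
                    lower.tail = FALSE)
    if (is.na(pf) || pf >= gate_alpha) next
    fit <- lowess(cov[o], v[o, j], f = span)
    trend <- approx(fit$x, fit$y, xout = cov, rule = 2, ties = mean)$y
    v[, j] <- v[, j] - trend + mean(trend)
  }
  nm$values <- v
  nm$provenance <- c(nm$provenance, paste0("within_sample:", covariate))
  nm
}

#' Between-sample normalization
#'
#' `upper_quartile` shifts each column so the 75th percentiles of expressed
#' genes agree; "expressed" is any value strictly above the column floor
#' (the pseudo-count level of zero-count genes).  `full_quantile` forces
#' all columns onto one empirical distribution (the mean of the sorted
#' columns; ties broken by position, so sorted columns are exactly equal
#' afterwards).
#'
#' @param x A `norm_matrix` (or `count_matrix`).
#' @param method `"upper_quartile"` or `"full_quantile"`.
#' @return A `norm_matrix`.
#' @export
between_sample_normalize <- function(x, method = c("upper_quartile",
                                                   "full_quantile")) {
  method <- match.arg(method)
  nm <- as_norm_matrix(x)
  v <- nm$values
  if (ncol(v) < 2) abort("need at least 2 samples", "format_error")
  if (any(apply(v, 2, function(col) all(col <= min(col) + 1e-12))))
    abort("a sample has no expressed genes", "normalization_error")
  if (method == "upper_quartile") {
    uq <- apply(v, 2, function(col)
      quantile(col[col > min(col) + 1e-12], 0.75, names = FALSE))
    v <- sweep(v, 2, uq - mean(uq))
  } else {
    ref <- rowMeans(apply(v, 2, sort))
    for (j in seq_len(ncol(v))) v[order(v[, j]), j] <- ref
  }
  nm$values <- v
  nm$provenance <- c(nm$provenance, paste0("between_sample:", method))
  nm
}

#' Remove batch effects by per-gene linear modeling
#'
#' Per gene, fits `log2 expression ~ group + batch` by least squares and
#' subtracts the fitted batch component, preserving biological group
#' structure.  Errors when batch is perfectly confounded with group.
#'
#' @param x A `norm_matrix` (or `count_matrix`).
#' @param batch_labels Factor-like, one per sample; defaults to the
#'   `center` column of the sample sheet.
#' @param group_labels Optional biological grouping (e.g. subtype) to
#'   protect; defaults to the `subtype` column when present (NA mapped to
#'   its own level).
#' @return A `norm_matrix`; attribute `batch_fit` holds per-gene batch
#'   coefficient estimates and standard errors (treatment contrasts
#'   against the first batch level).
#' @export
remove_batch_effect <- function(x, batch_labels = NULL, group_labels = NULL) {
  nm <- as_norm_matrix(x)
  v <- nm$values
  if (is.null(batch_labels)) batch_labels <- nm$sample_meta$center
  if (is.null(group_labels) && !is.null(nm$sample_meta$subtype))
    group_labels <- nm$sample_meta$subtype
  batch <- factor(batch_labels)
  if (nlevels(batch) < 2) abort("need >= 2 batches", "format_error")
  if (is.null(group_labels)) {
    design <- stats::model.matrix(~ 1, data.frame(row.names = colnames(v)))
  } else {
    group <- factor(ifelse(is.na(group_labels), ".na", as.character(group_labels)))
    if (nlevels(group) > 1 &&
        all(rowSums(table(group, batch) > 0) <= 1))
      abort("batch perfectly confounded with group", "confounding_error")
    design <- stats::model.matrix(~ group)
  }
  bmat <- stats::model.matrix(~ batch)[, -1, drop = FALSE]
  X <- cbind(design, bmat)
  if (qr(X)$rank < ncol(X))
    abort("batch perfectly confounded with group", "confounding_error")
  fit <- lm.fit(X, t(v))
  cf <- fit$coefficients
  bidx <- seq.int(ncol(design) + 1L, ncol(X))
  batch_part <- t(bmat %*% cf[bidx, , drop = FALSE])
  # standard errors of batch coefficients
  XtXinv <- chol2inv(chol(crossprod(X)))
  df <- ncol(v) - ncol(X)
  rss <- colSums(as.matrix(fit$residuals)^2)
  sigma2 <- rss / max(df, 1)
  se <- sqrt(outer(sigma2, diag(XtXinv)[bidx]))
  colnames(se) <- colnames(X)[bidx]
  nm$values <- v - batch_part
  nm$provenance <- c(nm$provenance, "batch_removal:lsq")
  attr(nm, "batch_fit") <- list(
    coefficients = t(cf[bidx, , drop = FALSE]), se = se,
    batch_levels = levels(batch), df = df)
  nm
}

#' Classical MDS embedding of samples
#'
#' Classical multidimensional scaling on Euclidean distances over the 500
#' most variable genes (fewer when the matrix is smaller).  Coordinates
#' are sign-fixed (largest-magnitude loading positive per axis) so the
#' embedding is deterministic.
#'
#' @param x A `norm_matrix` (or `count_matrix`).
#' @param k Embedding dimension (default 2); must be < number of samples.
#' @param n_top Number of most-variable genes used (default 500).
#' @return Numeric matrix (samples x k).
#' @export
mds_embedding <- function(x, k = 2L, n_top = 500L) {
  nm <- as_norm_matrix(x)
  v <- nm$values
  if (ncol(v) < 3) abort("need >= 3 samples", "format_error")
  if (k >= ncol(v)) abort("k must be < number of samples", "dimension_error")
  vars <- apply(v, 1, var)
  top <- head(order(vars, decreasing = TRUE), min(n_top, nrow(v)))
  d <- dist(t(v[top, , drop = FALSE]))
  emb <- cmdscale(d, k = k)
  for (j in seq_len(ncol(emb))) {
    i <- which.max(abs(emb[, j]))
    if (emb[i, j] < 0) emb[, j] <- -emb[, j]
  }
  emb
}

#' Cluster samples into TF-defined subtypes
#'
#' Hierarchical clustering (Ward linkage on Euclidean distances of
#' z-scored TF expression rows) cut at `k` clusters.  With the canonical
#' six-TF panel this discriminates the T-ALL cohort into six subtype
#' clusters.
#'
#' @param x A `norm_matrix` (or `count_matrix`).
#' @param tf_list Genes defining the subtypes (default the six canonical
#'   TFs).
#' @param k Number of clusters (default 6).
#' @return Named integer vector: cluster id per sample.
#' @export
cluster_subtypes <- function(x, tf_list = tall_subtype_tfs, k = 6L) {
  nm <- as_norm_matrix(x)
  missing <- setdiff(tf_list, rownames(nm$values))
  if (length(missing))
    abort(paste("TF(s) absent from the matrix:",
                paste(missing, collapse = ",")), "annotation_error")
  v <- nm$values[tf_list, , drop = FALSE]
  z <- t(scale(t(v)))
  z[is.nan(z)] <- 0
  ord <- order(colnames(v))  # input-order invariance
  hc <- hclust(dist(t(z[, ord, drop = FALSE])), method = "ward.D2")
  cl <- cutree(hc, k = min(k, ncol(v)))
  cl[match(colnames(v), colnames(v)[ord])]
}
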