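# Recurrence-based driver selection and cohort mutation-burden statistics.

#' Select recurrently mutated genes
#'
#' A gene is selected when it carries a protein-altering mutation in at
#' least `min_recurrence` distinct *patient* samples; multiple variants in
#' one sample count once, and cell lines and thymus are excluded from the
#' recurrence count (their hits are reported as annotation).
#'
#' @param calls Protein-altering variant table with `gene_id`, `sample_id`,
#'   `variant_id`.
#' @param sample_meta Sample sheet with `sample_id`, `sample_type`.
#' @param min_recurrence Minimum number of distinct mutated patients
#'   (default 2).
#' @return A `recurrence_result` list: `gene_patients` (named list of
#'   patient-sample sets per gene), `selected` (character vector),
#'   `cellline_hits` (named list), `per_sample_counts` (named integer:
#'   protein-altering variants per sample, zero-filled over the sample
#'   sheet), `min_recurrence`.
#' @export
select_recurrent_genes <- function(calls, sample_meta, min_recurrence = 2L) {
  unknown <- setdiff(unique(calls$sample_id), sample_meta$sample_id)
  if (length(unknown))
    abort(paste("unknown sample(s) in calls:", paste(unknown, collapse = ",")),
          "pairing_error")
  stype <- setNames(sample_meta$sample_type, sample_meta$sample_id)
  calls <- unique(calls[, c("gene_id", "sample_id", "variant_id")])
  is_pat <- stype[calls$sample_id] == "patient"
  gene_patients <- lapply(
    split(calls$sample_id[is_pat], calls$gene_id[is_pat]), unique)
  cellline_hits <- lapply(
    split(calls$sample_id[!is_pat], calls$gene_id[!is_pat]), unique)
  selected <- names(gene_patients)[
    vapply(gene_patients, length, integer(1)) >= min_recurrence]
  per_variant <- unique(calls[, c("sample_id", "variant_id")])
  tab <- table(factor(per_variant$sample_id, levels = sample_meta$sample_id))
  structure(list(gene_patients = gene_patients,
                 selected = sort(selected),
                 cellline_hits = cellline_hits,
                 per_sample_counts = setNames(as.integer(tab), names(tab)),
                 min_recurrence = min_recurrence),
            class = "recurrence_result")
}

#' Compare mutation burden between sample groups
#'
#' Two-sided Mann-Whitney U test of per-sample mutation counts between two
#' sample types (default cell lines versus patients).  The p-value is by
#' exact enumeration when both groups have at most 12 samples (all
#' assignments enumerated when ties are present, the exact Wilcoxon
#' distribution otherwise); larger groups use the normal approximation
#' with tie correction.
#'
#' @param per_sample_counts Named integer vector of mutation counts.
#' @param sample_meta Sample sheet with `sample_id`, `sample_type`.
#' @param groups Character(2): the two `sample_type` levels to compare.
#' @return List with `U` (Mann-Whitney U for the first group), `p_value`,
#'   `n` (per-group sizes), `method`.
#' @export
compare_mutation_burden <- function(per_sample_counts, sample_meta,
                                    groups = c("cell_line", "patient")) {
  stype <- setNames(sample_meta$sample_type, sample_meta$sample_id)
  x <- per_sample_counts[names(per_sample_counts)[
    stype[names(per_sample_counts)] == groups[1]]]
  y <- per_sample_counts[names(per_sample_counts)[
    stype[names(per_sample_counts)] == groups[2]]]
  if (length(x) < 2 || length(y) < 2)
    abort("each group needs at least 2 samples", "statistics_error")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 <= 12 && n2 <= 12) {
    if (!ties) {
      p <- wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
      method <- "exact"
    } else {
      # enumerate all assignments of the pooled values to group 1
      pool <- c(x, y)
      combs <- combn(n1 + n2, n1)
      rr <- rank(pool)
      stats <- apply(combs, 2, function(idx)
        sum(rr[idx]) - n1 * (n1 + 1) / 2)
      mu <- n1 * n2 / 2
      p <- mean(abs(stats - mu) >= abs(U - mu) - 1e-9)
      method <- "exact_enumeration_ties"
    }
  } else {
    p <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    method <- "normal_approximation"
  }
  list(U = U, p_value = min(1, p), n = c(n1, n2), method = method)
}

#' Median mutation burden of a sample group
#'
#' @param per_sample_counts Named integer vector.
#' @param sample_meta Sample sheet.
#' @param group A `sample_type` level (default `"patient"`); `NULL` uses
#'   all samples present in `per_sample_counts`.
#' @return Numeric median (mean of the central pair for even n).
#' @export
median_burden <- function(per_sample_counts, sample_meta = NULL,
                          group = NULL) {
  x <- per_sample_counts
  if (!is.null(group)) {
    stype <- setNames(sample_meta$sample_type, sample_meta$sample_id)
    x <- x[names(x)[stype[names(x)] == group]]
  }
  if (!length(x)) abort("empty group", "statistics_error")
  median(x)
}
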