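# Junction-based exon-skipping statistics: PSI-style skipping ratio,
# Fisher exact tumor-vs-control test, and a BH-corrected cohort scan.

#' Exon-skipping ratio from junction counts
#'
#' `C / (A + B + C)` where `A` and `B` are the two inclusion junctions
#' flanking the candidate exon and `C` is the skipping junction; a
#' one-junction event sets `B = 0`.  This is the maximum-likelihood
#' binomial estimate of the fraction of transcripts skipping the exon.
#'
#' @param A,B,C Non-negative integer junction read counts (vectorized).
#' @return Numeric ratio(s) in [0, 1].
#' @export
skipping_ratio <- function(A, B = 0L, C) {
  if (any(A < 0 | B < 0 | C < 0)) abort("negative junction count",
                                        "format_error")
  tot <- A + B + C
  if (any(tot == 0)) abort("undefined ratio: all junction counts zero",
                           "ratio_error")
  C / tot
}

#' Test an exon-skipping event against a control sample
#'
#' Two-sided Fisher exact test on the 2x2 table of inclusion (`A+B`)
#' versus skipping (`C`) reads in tumor and control.
#'
#' @param tumor,control Numeric length-3 vectors `(A, B, C)`.
#' @return The p-value.
#' @export
test_skipping_vs_control <- function(tumor, control) {
  stopifnot(length(tumor) == 3, length(control) == 3)
  if (sum(tumor) == 0 || sum(control) == 0)
    abort("zero junction totals", "input_error")
  tab <- matrix(c(tumor[1] + tumor[2], tumor[3],
                  control[1] + control[2], control[3]), 2, 2)
  fisher.test(round(tab))$p.value
}

#' Scan junction tables for significant exon-skipping events
#'
#' Tests every (event, tumor sample) pair against the control sample with
#' the Fisher junction test and applies Benjamini-Hochberg correction
#' across all tested pairs.  Optionally restricted to a gene list (e.g.
#' the curated driver genes).
#'
#' @param junctions Junction table: `event_id`, `gene_id`, `sample_id`,
#'   `A`, `B`, `C`.
#' @param control_sample Control (thymus) sample id; must be present.
#' @param alpha BH false-discovery threshold (default 0.05).
#' @param gene_list Optional gene restriction.
#' @return Data frame of tested pairs with `psi`, `psi_control`,
#'   `p_value`, `q_value`, `significant`, sorted by p.
#' @export
scan_events <- function(junctions, control_sample, alpha = 0.05,
                        gene_list = NULL) {
  if (!control_sample %in% junctions$sample_id)
    abort("control sample absent from junction table", "input_error")
  if (!is.null(gene_list))
    junctions <- junctions[junctions$gene_id %in% gene_list, , drop = FALSE]
  ctrl <- junctions[junctions$sample_id == control_sample, , drop = FALSE]
  tum <- junctions[junctions$sample_id != control_sample, , drop = FALSE]
  tum <- tum[(tum$A + tum$B + tum$C) > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tum)), function(i) {
    cc <- ctrl[ctrl$event_id == tum$event_id[i], , drop = FALSE]
    if (nrow(cc) == 0 || (cc$A + cc$B + cc$C) == 0) return(NULL)
    data.frame(
      event_id = tum$event_id[i], gene_id = tum$gene_id[i],
      sample_id = tum$sample_id[i],
      psi = skipping_ratio(tum$A[i], tum$B[i], tum$C[i]),
      psi_control = skipping_ratio(cc$A[1], cc$B[1], cc$C[1]),
      p_value = test_skipping_vs_control(
        c(tum$A[i], tum$B[i], tum$C[i]), c(cc$A[1], cc$B[1], cc$C[1])),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(event_id = character(), gene_id = character(),
                      sample_id = character(), psi = numeric(),
                      psi_control = numeric(), p_value = numeric(),
                      q_value = numeric(), significant = logical()))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= alpha & alpha > 0
  out[order(out$p_value), , drop = FALSE]
}
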