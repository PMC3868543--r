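# Fusion-candidate triage: support/annotation filters, flanking-gene
# expression scan, and consequence classification (chimeric protein /
# partner over-expression / partner inactivation).

#' Filter fusion candidates
#'
#' A candidate is retained when it has at least `min_spanning` spanning
#' reads AND at least `min_split` split reads, neither partner is
#' ribosomal or mitochondrial, and the partners are not adjacent genes on
#' one chromosome (read-through/trans-splicing artifacts).  Adjacency is
#' rank-consecutive gene order; `require_both = FALSE` switches the read
#' support rule to OR.
#'
#' @param candidates Fusion table with `gene5p`, `gene3p`,
#'   `spanning_reads`, `split_reads` (see
#'   [simulate_fusions_and_junctions()]).
#' @param gene_models Gene annotation covering all partners.
#' @param min_spanning,min_split Support thresholds (defaults 8 and 5).
#' @param require_both Require both support thresholds (default TRUE).
#' @return `candidates` with added columns `retained` (logical) and
#'   `filter_rule` (first failing rule or `"retained"`).
#' @export
filter_fusion_candidates <- function(candidates, gene_models,
                                     min_spanning = 8L, min_split = 5L,
                                     require_both = TRUE) {
  gm <- gene_models
  missing <- setdiff(unique(c(candidates$gene5p, candidates$gene3p)),
                     gm$gene_id)
  if (length(missing))
    abort(paste("fusion partner(s) absent from gene model:",
                paste(missing, collapse = ",")), "annotation_error")
  i5 <- match(candidates$gene5p, gm$gene_id)
  i3 <- match(candidates$gene3p, gm$gene_id)
  span_ok <- candidates$spanning_reads >= min_spanning
  split_ok <- candidates$split_reads >= min_split
  support_ok <- if (require_both) span_ok & split_ok else span_ok | split_ok
  ribo <- gm$is_ribosomal[i5] | gm$is_ribosomal[i3]
  mito <- gm$chrom[i5] == "chrM" | gm$chrom[i3] == "chrM"
  adjacent <- gm$chrom[i5] == gm$chrom[i3] &
    abs(gm$neighbor_rank[i5] - gm$neighbor_rank[i3]) == 1L
  rule <- rep("retained", nrow(candidates))
  rule[!support_ok] <- "read_support"
  rule[support_ok & ribo] <- "ribosomal_partner"
  rule[support_ok & !ribo & mito] <- "mitochondrial_partner"
  rule[support_ok & !ribo & !mito & adjacent] <- "adjacent_genes"
  candidates$retained <- rule == "retained"
  candidates$filter_rule <- rule
  candidates
}

#' Expression scan of a fusion partner and its genomic neighbors
#'
#' For the partner gene and each neighbor within `window` genes up- and
#' downstream (by genomic rank), computes the log2 fold change versus the
#' thymus control and the z-score of the carrier sample against the tumor
#' cohort, sorted by z-score.  Truncated windows at contig edges are
#' flagged.
#'
#' @param partner_gene Gene id.
#' @param x A `norm_matrix` (or `count_matrix`) containing the carrier and
#'   thymus columns.
#' @param carrier_sample,thymus_sample Column names.
#' @param gene_models Gene annotation defining neighbor order.
#' @param window Genes on each side (default 2; 0 = partner only).
#' @return Data frame `gene_id`, `offset` (gene-rank offset from partner),
#'   `log2fc_vs_thymus`, `zscore`, ordered by decreasing z; attribute
#'   `truncated` flags a clipped window.
#' @export
flanking_expression_scan <- function(partner_gene, x, carrier_sample,
                                     thymus_sample, gene_models,
                                     window = 2L) {
  nm <- as_norm_matrix(x)
  v <- nm$values
  if (!carrier_sample %in% colnames(v))
    abort("carrier sample absent from expression matrix", "evidence_error")
  if (!thymus_sample %in% colnames(v))
    abort("thymus sample absent from expression matrix", "evidence_error")
  gm <- gene_models
  i <- match(partner_gene, gm$gene_id)
  if (is.na(i)) abort("partner absent from gene model", "annotation_error")
  chrom_genes <- gm[gm$chrom == gm$chrom[i], ]
  chrom_genes <- chrom_genes[order(chrom_genes$neighbor_rank), ]
  r <- match(partner_gene, chrom_genes$gene_id)
  lo <- max(1L, r - window); hi <- min(nrow(chrom_genes), r + window)
  truncated <- (r - lo < window) || (hi - r < window)
  sel <- chrom_genes$gene_id[lo:hi]
  sel <- sel[sel %in% rownames(v)]
  cohort <- setdiff(colnames(v), thymus_sample)
  mu <- rowMeans(v[sel, cohort, drop = FALSE])
  sdv <- apply(v[sel, cohort, drop = FALSE], 1, sd)
  out <- data.frame(
    gene_id = sel,
    offset = chrom_genes$neighbor_rank[match(sel, chrom_genes$gene_id)] -
      chrom_genes$neighbor_rank[r],
    log2fc_vs_thymus = v[sel, carrier_sample] - v[sel, thymus_sample],
    zscore = (v[sel, carrier_sample] - mu) / ifelse(sdv == 0, NA, sdv),
    stringsAsFactors = FALSE)
  out <- out[order(-out$zscore), , drop = FALSE]
  attr(out, "truncated") <- truncated
  out
}

#' Classify the consequence of a retained fusion
#'
#' Decision tree: (1) an in-frame fusion between two coding partners
#' encodes a chimeric protein; (2) otherwise, if a partner or a
#' flanking-scan neighbor is strongly over-expressed in the carrier
#' (z >= `z_over` and log2 fold vs thymus >= `lfc_over`), the call is
#' partner over-expression naming the affected gene; (3) otherwise, if a
#' partner is tumor-suppressor-flagged or under-expressed
#' (z <= `z_under`), partner inactivation; (4) otherwise unclassified.
#'
#' @param call One retained row from [filter_fusion_candidates()].
#' @param x Normalized expression containing carrier and thymus columns.
#' @param gene_models Gene annotation (provides `is_tsg` flags).
#' @param thymus_sample Thymus column name.
#' @param window Flanking scan window (default 2).
#' @param z_over,lfc_over,z_under Evidence thresholds (defaults 2, 2
#'   log2 i.e. 4-fold, and -2).
#' @return List with `fusion_id`, `consequence_class`, `affected_gene`,
#'   `evidence` (scan rows or partner stats).
#' @export
classify_fusion_consequence <- function(call, x, gene_models,
                                        thymus_sample = "THYMUS",
                                        window = 2L, z_over = 2,
                                        lfc_over = 2, z_under = -2) {
  stopifnot(nrow(call) == 1)
  if (!isTRUE(call$retained))
    abort("consequence classification requires a retained candidate",
          "input_error")
  nm <- as_norm_matrix(x)
  gm <- gene_models
  carrier <- call$sample_id
  if (!carrier %in% colnames(nm$values))
    abort("carrier sample absent from expression matrix", "evidence_error")
  partners <- c(call$gene5p, call$gene3p)
  coding <- !gm$is_ribosomal[match(partners, gm$gene_id)] &
    gm$chrom[match(partners, gm$gene_id)] != "chrM"
  if (identical(call$frame_status, "in_frame") && all(coding)) {
    return(list(fusion_id = call$fusion_id,
                consequence_class = "chimeric_protein",
                affected_gene = NA_character_, evidence = NULL))
  }
  scans <- lapply(partners, function(g)
    flanking_expression_scan(g, nm, carrier, thymus_sample, gm, window))
  ev <- do.call(rbind, Map(function(s, g) {
    s$partner <- g; s
  }, scans, partners))
  over <- ev[!is.na(ev$zscore) & ev$zscore >= z_over &
               ev$log2fc_vs_thymus >= lfc_over, , drop = FALSE]
  if (nrow(over) > 0) {
    best <- over[which.max(over$zscore), ]
    return(list(fusion_id = call$fusion_id,
                consequence_class = "partner_overexpression",
                affected_gene = best$gene_id, evidence = ev))
  }
  pstats <- ev[ev$offset == 0, , drop = FALSE]
  tsg <- gm$is_tsg[match(partners, gm$gene_id)]
  under <- pstats[!is.na(pstats$zscore) & pstats$zscore <= z_under, ,
                  drop = FALSE]
  if (any(tsg) || nrow(under) > 0) {
    affected <- if (nrow(under) > 0) under$gene_id[which.min(under$zscore)]
                else partners[tsg][1]
    return(list(fusion_id = call$fusion_id,
                consequence_class = "partner_inactivation",
                affected_gene = affected, evidence = ev))
  }
  list(fusion_id = call$fusion_id, consequence_class = "unclassified",
       affected_gene = NA_character_, evidence = ev)
}

#' Triage and classify a full fusion candidate table
#'
#' Convenience wrapper: filters candidates, then classifies every retained
#' candidate.
#'
#' @inheritParams filter_fusion_candidates
#' @param x Normalized expression (or `count_matrix`).
#' @param thymus_sample Thymus column name.
#' @param ... Thresholds passed to [classify_fusion_consequence()].
#' @return The candidate table with `retained`, `filter_rule`,
#'   `consequence_class`, `affected_gene` columns.
#' @export
triage_fusions <- function(candidates, gene_models, x,
                           thymus_sample = "THYMUS",
                           min_spanning = 8L, min_split = 5L, ...) {
  calls <- filter_fusion_candidates(candidates, gene_models,
                                    min_spanning, min_split)
  calls$consequence_class <- NA_character_
  calls$affected_gene <- NA_character_
  for (i in which(calls$retained)) {
    res <- classify_fusion_consequence(calls[i, , drop = FALSE], x,
                                       gene_models, thymus_sample, ...)
    calls$consequence_class[i] <- res$consequence_class
    calls$affected_gene[i] <- res$affected_gene
  }
  calls
}
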