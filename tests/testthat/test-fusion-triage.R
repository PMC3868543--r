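# Fusion filtering boundaries, flanking expression scan, consequence
# classification.

fusion_row <- function(g5, g3, span, split, frame = "out_of_frame",
                       sample = "P01", id = "FX01") {
  data.frame(fusion_id = id, sample_id = sample, gene5p = g5, gene3p = g3,
             chrom5p = ".", pos5p = 1L, chrom3p = ".", pos3p = 1L,
             spanning_reads = span, split_reads = split,
             frame_status = frame, stringsAsFactors = FALSE)
}

test_that("support thresholds are exact at (8 spanning, 5 split)", {
  gm <- test_bundle()$gene_models
  clean <- gm$gene_id[!gm$is_ribosomal & !gm$is_chrM]
  g_a <- clean[match(TRUE, gm$chrom[match(clean, gm$gene_id)] == "chr1")]
  g_b <- clean[match(TRUE, gm$chrom[match(clean, gm$gene_id)] == "chr2")]
  at <- filter_fusion_candidates(fusion_row(g_a, g_b, 8L, 5L), gm)
  expect_true(at$retained)
  expect_false(filter_fusion_candidates(fusion_row(g_a, g_b, 20L, 4L),
                                        gm)$retained)
  expect_false(filter_fusion_candidates(fusion_row(g_a, g_b, 7L, 50L),
                                        gm)$retained)
  # OR semantics when configured
  expect_true(filter_fusion_candidates(fusion_row(g_a, g_b, 7L, 50L), gm,
                                       require_both = FALSE)$retained)
  expect_error(filter_fusion_candidates(fusion_row("NOPE", g_b, 9L, 9L), gm),
               class = "annotation_error")
})

test_that("annotation filters: adjacency, ribosomal and chrM partners", {
  gm <- test_bundle()$gene_models
  chr1 <- gm[gm$chrom == "chr1", ]
  chr1 <- chr1[order(chr1$neighbor_rank), ]
  adj <- filter_fusion_candidates(
    fusion_row(chr1$gene_id[1], chr1$gene_id[2], 30L, 20L), gm)
  expect_identical(adj$filter_rule, "adjacent_genes")
  non_adj <- filter_fusion_candidates(
    fusion_row(chr1$gene_id[1], chr1$gene_id[3], 30L, 20L), gm)
  expect_true(non_adj$retained)
  ribo <- gm$gene_id[gm$is_ribosomal][1]
  mito <- gm$gene_id[gm$is_chrM][1]
  clean <- gm$gene_id[!gm$is_ribosomal & !gm$is_chrM][5]
  expect_identical(filter_fusion_candidates(
    fusion_row(ribo, clean, 30L, 20L), gm)$filter_rule, "ribosomal_partner")
  expect_identical(filter_fusion_candidates(
    fusion_row(clean, mito, 30L, 20L), gm)$filter_rule,
    "mitochondrial_partner")
  # monotone in both thresholds; invariant under duplication
  cand <- test_bundle()$fusions
  n_ret <- function(sp, sl) sum(filter_fusion_candidates(cand, gm, sp,
                                                         sl)$retained)
  grid_sp <- vapply(c(0, 4, 8, 16, 32), n_ret, integer(1), sl = 5L)
  grid_sl <- vapply(c(0, 2, 5, 10, 20), n_ret, integer(1), sp = 8L)
  expect_true(all(diff(grid_sp) <= 0) && all(diff(grid_sl) <= 0))
  dup <- filter_fusion_candidates(rbind(cand, cand[1, ]), gm)
  expect_identical(sum(dup$retained[seq_len(nrow(cand))]),
                   sum(filter_fusion_candidates(cand, gm)$retained))
})

test_that("flanking scan surfaces the coupled neighbor with z > 2", {
  b <- test_bundle()
  nm <- test_norm()
  tr <- b$truth$fusions
  over <- merge(b$fusions, tr[tr$class == "partner_overexpression", ],
                by = "fusion_id")
  for (i in seq_len(nrow(over))) {
    scan <- flanking_expression_scan(over$gene3p[i], nm, over$sample_id[i],
                                     "THYMUS", b$gene_models, window = 2)
    expect_identical(scan$gene_id[1], over$affected_gene[i])
    expect_gt(scan$zscore[1], 2)
  }
  # window 0 evaluates only the partner itself
  w0 <- flanking_expression_scan(over$gene3p[1], nm, over$sample_id[1],
                                 "THYMUS", b$gene_models, window = 0)
  expect_identical(nrow(w0), 1L)
  expect_identical(w0$gene_id, over$gene3p[1])
  # null: genes without coupled changes do not pass the combined
  # over-expression evidence (z >= 2 AND >= 4-fold vs thymus)
  affected <- stats::na.omit(tr$affected_gene)
  pool <- setdiff(rownames(nm$values), c(affected, tall_subtype_tfs))
  withr::with_seed(51, picks <- sample(pool, 10))
  hits <- 0L
  for (g in picks) {
    scan <- flanking_expression_scan(g, nm, "P03", "THYMUS", b$gene_models)
    hits <- hits + sum(scan$zscore >= 2 & scan$log2fc_vs_thymus >= 2,
                       na.rm = TRUE)
  }
  expect_lte(hits, 1L)
})

test_that("consequence classification recovers all three planted classes", {
  b <- test_bundle()
  nm <- test_norm()
  calls <- triage_fusions(b$fusions, b$gene_models, nm)
  m <- merge(calls, b$truth$fusions, by = "fusion_id")
  truecl <- m[!grepl("^decoy", m$class), ]
  expect_true(all(truecl$retained))
  expect_identical(truecl$consequence_class, truecl$class)
  ov <- truecl[truecl$class == "partner_overexpression", ]
  expect_identical(ov$affected_gene.x, ov$affected_gene.y)
  # decoys are all removed by construction
  expect_false(any(m$retained[grepl("^decoy", m$class)]))
  # classification refuses removed candidates
  removed <- calls[!calls$retained, ][1, ]
  expect_error(classify_fusion_consequence(removed, nm, b$gene_models),
               class = "input_error")
})

test_that("retained true fusions scale linearly with the planted count", {
  ns <- c(2L, 4L, 6L)
  retained <- vapply(ns, function(k) {
    cfg <- sim_config(n_patients = 8L, n_celllines = 0L, n_genes = 200L,
                      germline_rate = 5, n_true_fusions = k,
                      n_decoy_fusions = 8L, seed = 60L)
    bb <- simulate_cohort(cfg)
    sum(filter_fusion_candidates(bb$fusions, bb$gene_models)$retained)
  }, integer(1))
  expect_identical(retained, ns)
})
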