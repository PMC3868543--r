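# Normalization, batch removal, MDS diagnostics and subtype clustering.

test_that("within-sample normalization removes a planted GC trend only", {
  cfg <- sim_config(n_patients = 8L, n_celllines = 4L, n_genes = 2000L,
                    batch_effect_sd = 0, gc_bias_slope = 0,
                    length_bias_exponent = 0, seed = 31L)
  cm <- simulate_counts(cfg, simulate_gene_models(cfg, 31), 31)
  nm0 <- as_norm_matrix(cm)
  nm1 <- within_sample_normalize(cm, "gc")
  expect_lt(max(abs(nm1$values - nm0$values)), 0.1)   # nothing to remove
  expect_true(any(grepl("within_sample:gc", nm1$provenance)))

  cfg2 <- sim_config(n_patients = 8L, n_celllines = 4L, n_genes = 2000L,
                     batch_effect_sd = 0, gc_bias_slope = 2,
                     length_bias_exponent = 0, seed = 32L)
  cm2 <- simulate_counts(cfg2, simulate_gene_models(cfg2, 32), 32)
  nm2 <- within_sample_normalize(cm2, "gc")
  # the planted GC bias is a symmetric hump: correlate against its shape
  hump <- 1 - ((cm2$gene_annot$gc - 0.5) / 0.3)^2
  r_pre <- cor(rowMeans(as_norm_matrix(cm2)$values), hump)
  r_post <- cor(rowMeans(nm2$values), hump)
  expect_gt(abs(r_pre), 0.3)
  expect_lt(abs(r_post), 0.1)
  # identical input columns stay identical
  ident <- cm2
  ident$counts[, 2] <- ident$counts[, 1]
  out <- within_sample_normalize(ident, "gc")
  expect_identical(unname(out$values[, 1]), unname(out$values[, 2]))
  # constant covariate is a warning no-op
  flat <- cm2; flat$gene_annot$gc <- 0.5
  expect_warning(within_sample_normalize(flat, "gc"), "constant covariate")
})

test_that("between-sample normalization aligns columns as specified", {
  b <- test_bundle()
  nm <- as_norm_matrix(b$count_matrix)
  shifted <- nm
  shifted$values[, 2] <- shifted$values[, 1] + 1   # pure scale shift
  uq <- between_sample_normalize(shifted, "upper_quartile")
  expect_equal(uq$values[, 1], uq$values[, 2], tolerance = 1e-10,
               ignore_attr = TRUE)
  fq <- between_sample_normalize(nm, "full_quantile")
  srt <- apply(fq$values, 2, sort)
  expect_lt(max(abs(srt - srt[, 1])), 1e-8)
  # planted library-size fold changes 0.25-4x are removed
  withr::with_seed(33, fold <- 2^runif(ncol(nm$values), -2, 2))
  scaled <- nm
  scaled$values <- sweep(nm$values, 2, log2(fold), `+`)
  fixed <- between_sample_normalize(scaled, "upper_quartile")
  uqs <- apply(fixed$values, 2, function(col)
    quantile(col[col > min(col) + 1e-12], 0.75, names = FALSE))
  expect_lt(max(uqs) - min(uqs), 1e-6)
  zero <- nm
  zero$values[, 1] <- min(nm$values)
  expect_error(between_sample_normalize(zero), class = "normalization_error")
})

test_that("batch removal recovers planted shifts and corrects clustering", {
  b <- test_bundle()
  nm <- test_norm()
  fit <- attr(nm, "batch_fit")
  truth <- b$truth$batch_shifts
  true_diff <- truth[, 2] - truth[, 1]     # treatment contrast vs center1
  expressed <- rowMeans(b$count_matrix$counts) >= 10
  est <- fit$coefficients[, 1]
  se <- fit$se[, 1]
  within3 <- abs(est - true_diff)[expressed] <= 3 * se[expressed]
  expect_gt(mean(within3), 0.95)
  # batch F-statistic drops after removal
  pre <- as_norm_matrix(b$count_matrix)
  fstat <- function(v, batch) {
    batch <- factor(batch)
    apply(v, 1, function(y) {
      a <- stats::anova(stats::lm(y ~ batch))
      a$`F value`[1]
    })
  }
  idx <- which(expressed)[1:100]           # 100 genes suffice for the median
  f_pre <- fstat(pre$values[idx, ], b$sample_meta$center)
  f_post <- fstat(nm$values[idx, ], b$sample_meta$center)
  expect_lt(median(f_post), median(f_pre))
  # MDS silhouettes: batch dominates before, subtype after
  tum <- b$sample_meta$sample_type != "thymus"
  d_pre <- dist(mds_embedding(pre)[tum, ])
  d_post <- dist(mds_embedding(nm)[tum, ])
  batch <- b$sample_meta$center[tum]
  subtype <- b$sample_meta$subtype[tum]
  expect_gt(mean_silhouette(d_pre, batch), mean_silhouette(d_post, batch))
  expect_lt(mean_silhouette(d_post, batch), mean_silhouette(d_post, subtype))
  # switched-off batch effect: removal is a near no-op
  cfg0 <- sim_config(n_patients = 8L, n_celllines = 4L, n_genes = 300L,
                     batch_effect_sd = 0, seed = 34L)
  cm0 <- simulate_counts(cfg0, simulate_gene_models(cfg0, 34), 34)
  nm0 <- as_norm_matrix(cm0)
  out0 <- remove_batch_effect(nm0)
  expect_lt(max(abs(out0$values - nm0$values)), 1.5)  # bounded by fit noise
  expect_lt(mean(abs(out0$values - nm0$values)), 0.2)
  # perfectly confounded design errors
  conf <- nm0
  expect_error(remove_batch_effect(conf, batch_labels = conf$sample_meta$subtype,
                                   group_labels = conf$sample_meta$subtype),
               class = "confounding_error")
})

test_that("MDS embedding is exact on planar configurations", {
  # three equidistant samples embed as an equilateral triangle
  v <- matrix(0, 10, 3, dimnames = list(paste0("g", 1:10), c("a", "b", "c")))
  v[1, 1] <- v[2, 2] <- v[3, 3] <- 2
  nm <- structure(list(values = v, provenance = "log2"), class = "norm_matrix")
  emb <- mds_embedding(nm, k = 2, n_top = 10)
  d <- as.vector(dist(emb))
  expect_lt(max(d) - min(d), 1e-9)
  # points already planar are reproduced exactly
  withr::with_seed(35, xy <- matrix(rnorm(2 * 12), 2, 12))
  v2 <- rbind(xy, matrix(0, 8, 12))
  rownames(v2) <- paste0("g", 1:10); colnames(v2) <- paste0("s", 1:12)
  nm2 <- structure(list(values = v2, provenance = "log2"),
                   class = "norm_matrix")
  emb2 <- mds_embedding(nm2, k = 2, n_top = 10)
  expect_equal(as.vector(dist(emb2)), as.vector(dist(t(xy))),
               tolerance = 1e-9)
  expect_error(mds_embedding(nm2, k = 12), class = "dimension_error")
  # large planted batch shift separates in the embedding
  cfg <- sim_config(n_patients = 10L, n_celllines = 6L, n_genes = 400L,
                    batch_effect_sd = 2, seed = 36L)
  cm <- simulate_counts(cfg, simulate_gene_models(cfg, 36), 36)
  emb3 <- mds_embedding(cm)
  sil <- mean_silhouette(dist(emb3), cm$sample_meta$center)
  expect_gt(sil, 0.5)
})

test_that("subtype clustering recovers the planted programs", {
  b <- test_bundle()
  nm <- test_norm()
  cl <- cluster_subtypes(nm)
  truth <- b$sample_meta$subtype[match(names(cl), b$sample_meta$sample_id)]
  tum <- !is.na(truth)
  expect_gte(adjusted_rand_index(cl[tum], truth[tum]), 0.9)
  # k = 1 puts everything in one cluster
  expect_true(all(cluster_subtypes(nm, k = 1) == 1L))
  # permuting sample order leaves the partition unchanged
  perm <- withr::with_seed(37, sample(ncol(nm$values)))
  nm_p <- nm
  nm_p$values <- nm$values[, perm]
  cl_p <- cluster_subtypes(nm_p)
  expect_identical(cl_p[names(cl)], cl)
  expect_error(cluster_subtypes(nm, tf_list = c("TAL1", "NOT_A_GENE")),
               class = "annotation_error")
})
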