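# Template matching, fold-change rankings, and gene-set enrichment.

rand_nm <- function(n_genes, n_samples, seed, rownames_prefix = "g") {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(paste0(rownames_prefix, seq_len(n_genes)),
                                paste0("s", seq_len(n_samples))))
  })
  structure(list(values = v, provenance = "log2"), class = "norm_matrix")
}

test_that("PTM finds planted neighbors and excludes the template", {
  nm <- rand_nm(50, 49, seed = 41)
  tpl <- nm$values["g1", ]
  withr::with_seed(42, {
    nm$values["g2", ] <- 0.95 * scale(tpl)[, 1] +
      sqrt(1 - 0.95^2) * rnorm(49)
  })
  nm$values["g3", ] <- tpl                     # identical profile, r = 1
  res <- ptm_neighbors(nm, "g1", p_threshold = 1e-5)
  expect_false("g1" %in% res$gene_id)          # template excluded
  expect_true(all(c("g2", "g3") %in% res$gene_id))
  expect_equal(res$pearson_r[res$gene_id == "g3"], 1, tolerance = 1e-12)
  expect_gt(res$pearson_r[res$gene_id == "g2"], 0.85)
  # p decreases with |r| at fixed n
  expect_true(all(diff(res$p_value) >= 0))
  expect_error(ptm_neighbors(nm, "absent"), class = "annotation_error")
  flat <- nm; flat$values["g1", ] <- 1
  expect_error(ptm_neighbors(flat, "g1"), class = "statistics_error")
})

test_that("PTM parametric p matches a permutation p at small n", {
  nm <- rand_nm(30, 10, seed = 43)
  tpl <- nm$values["g1", ]
  res <- ptm_neighbors(nm, "g1", p_threshold = 1)
  for (g in c("g2", "g9")) {
    prof <- nm$values[g, ]
    perm_r <- withr::with_seed(44, vapply(1:4000, function(i)
      cor(sample(tpl), prof), numeric(1)))
    p_perm <- mean(abs(perm_r) >= abs(res$pearson_r[res$gene_id == g]))
    p_par <- res$p_value[res$gene_id == g]
    expect_lt(abs(p_perm - p_par), 3 * sqrt(p_par * (1 - p_par) / 4000) + 0.02)
  }
})

test_that("PTM null calibration: ~1e-5 threshold yields almost no hits", {
  hits <- 0L
  for (s in 1:20) {
    nm <- rand_nm(2000, 49, seed = 100 + s)
    hits <- hits + nrow(ptm_neighbors(nm, "g1", p_threshold = 1e-5))
  }
  expect_lte(hits, 1L)
})

test_that("group LFC ranking behaves under construction and symmetry", {
  nm <- rand_nm(200, 24, seed = 45)
  grp <- rep(c(TRUE, FALSE), each = 12)
  nm$values["g7", grp] <- nm$values["g7", grp] + 5    # marker
  nm$values["g8", grp] <- nm$values["g8", grp] + 3    # co-boosted
  rk <- rank_by_group_lfc(nm, marker_gene = "g7")
  expect_lte(match("g8", names(rk)), 20)              # top decile
  rk_dir <- rank_by_group_lfc(nm, sample_groups = grp)
  rk_swap <- rank_by_group_lfc(nm, sample_groups = !grp)
  expect_equal(rk_dir[names(rk_swap)], -rk_swap, tolerance = 1e-12)
  same <- nm
  same$values <- cbind(nm$values[, 1:12], nm$values[, 1:12])
  colnames(same$values) <- paste0("s", 1:24)
  expect_equal(max(abs(rank_by_group_lfc(same, sample_groups = grp))), 0)
  expect_error(rank_by_group_lfc(nm, sample_groups = rep(TRUE, 24)),
               class = "grouping_error")
})

test_that("GSEA score equals the running-sum extremum (full-profile oracle)", {
  withr::with_seed(46, {
    ranking <- sort(rnorm(1000), decreasing = TRUE)
    names(ranking) <- paste0("g", sample(1000))
  })
  for (seed in 1:5) {
    gene_set <- withr::with_seed(seed, sample(names(ranking), 25))
    res <- gsea_enrichment(ranking, gene_set, n_perm = 10, seed = 1)
    prof <- res$running_sum
    oracle <- if (max(prof) >= -min(prof)) max(prof) else min(prof)
    expect_equal(res$es, oracle, tolerance = 1e-12)
  }
  # extreme concentration: set == top 10 -> ES > 0.9
  top <- gsea_enrichment(ranking, names(ranking)[1:10], n_perm = 50, seed = 1)
  expect_gt(top$es, 0.9)
  expect_error(gsea_enrichment(ranking, c("nope1", "nope2", "nope3",
                                          "nope4", "nope5")),
               class = "input_error")
  expect_error(gsea_enrichment(ranking, names(ranking)[1:3]),
               class = "input_error")
})

test_that("GSEA: classic KS mode invariant under monotone metric transforms", {
  withr::with_seed(47, {
    ranking <- sort(rexp(400), decreasing = TRUE)
    names(ranking) <- paste0("g", sample(400))
    gene_set <- sample(names(ranking), 20)
  })
  e1 <- gsea_enrichment(ranking, gene_set, n_perm = 10, seed = 2,
                        exponent = 0)
  mono <- sort(log1p(ranking) + 3, decreasing = TRUE)   # order-preserving
  e2 <- gsea_enrichment(mono, gene_set, n_perm = 10, seed = 2, exponent = 0)
  expect_equal(e1$es, e2$es, tolerance = 1e-12)
})

test_that("GSEA permutation p is uniform under the null", {
  withr::with_seed(48, {
    ranking <- sort(rnorm(500), decreasing = TRUE)
    names(ranking) <- paste0("g", sample(500))
  })
  ps <- vapply(1:200, function(s) {
    gs <- withr::with_seed(1000 + s, sample(names(ranking), 15))
    gsea_enrichment(ranking, gs, n_perm = 500, seed = s)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted subtype signature is enriched in the TF ranking", {
  b <- test_bundle()
  nm <- test_norm()
  sig <- b$truth$subtype_signatures[["TAL1"]]
  ranking <- rank_by_group_lfc(nm, marker_gene = "TAL1")
  res <- gsea_enrichment(ranking, sig, n_perm = 500, seed = 7)
  expect_gt(res$es, 0)
  expect_lt(res$p_value, 0.05)
  # PTM on the cohort: planted co-regulated targets correlate with the TF
  neigh <- ptm_neighbors(nm, "TAL1", p_threshold = 1e-5)
  expect_gt(length(intersect(neigh$gene_id, sig)), length(sig) / 2)
})
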