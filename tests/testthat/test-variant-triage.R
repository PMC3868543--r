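# Filter cascade, genotype bins, homopolymer rule, protein-altering
# selection, and the cascade's invariants.

test_that("genotype bins are deterministic with the decided boundaries", {
  expect_identical(classify_genotype(1.0, 50), "hom_var")
  expect_identical(classify_genotype(0.5, 50), "het")
  expect_identical(classify_genotype(0.19, 50), "hom_ref")
  expect_identical(classify_genotype(0.2, 50), "het")
  expect_identical(classify_genotype(0.8, 50), "hom_var")
  expect_error(classify_genotype(0.5, 0), class = "genotype_error")
})

test_that("homopolymer run length counts the longest run touching the anchor", {
  expect_identical(homopolymer_run_length("TTAAAAAAG", 5L), 6L)
  expect_identical(homopolymer_run_length("TTAAAAAG", 4L), 5L)
  # run of exactly 5 is NOT filtered at the strictly-greater threshold
  call5 <- make_call(is_indel = TRUE, homopolymer_context = "TTAAAAAG",
                     anchor_pos = 4L,
                     consequence_terms = "frameshift-variant")
  expect_true(filter_indels(call5)$trace$status[[1]] == "retained")
  call6 <- make_call(is_indel = TRUE, homopolymer_context = "TTAAAAAAG",
                     anchor_pos = 5L,
                     consequence_terms = "frameshift-variant")
  expect_identical(unname(filter_indels(call6)$trace$status[1]), "homopolymer")
  expect_error(homopolymer_run_length("TTXAA", 3L), class = "format_error")
})

test_that("homopolymer rule matches a brute-force scan on random 20-mers", {
  oracle <- function(s, a) {
    ch <- strsplit(s, "")[[1]]
    best <- 0L
    for (st in seq_along(ch)) {
      en <- st
      while (en < length(ch) && ch[en + 1] == ch[st]) en <- en + 1L
      if (st <= a + 1L && en >= a - 1L) best <- max(best, en - st + 1L)
    }
    best
  }
  withr::with_seed(99, {
    for (i in 1:50) {
      s <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE,
                        prob = c(.4, .2, .2, .2)), collapse = "")
      expect_identical(homopolymer_run_length(s, 10L), oracle(s, 10L))
    }
  })
})

test_that("SNV cascade applies its rules in order with a telescoping trace", {
  calls <- rbind(
    make_call(variant_id = "a", depth = 19L, vaf = 0.5),
    make_call(variant_id = "b", depth = 100L, vaf = 0.45, in_dbsnp = TRUE,
              in_cosmic = TRUE),                       # JAK3-A572V pattern
    make_call(variant_id = "c", depth = 100L, vaf = 0.45, in_repeat = TRUE,
              in_cosmic = TRUE),                       # repeat not rescued
    make_call(variant_id = "d", depth = 100L, vaf = 0.1),
    make_call(variant_id = "e", read_end_only = TRUE),
    make_call(variant_id = "f", in_dbsnp = TRUE),
    make_call(variant_id = "g", in_thymus = TRUE))
  res <- filter_snvs(calls)
  st <- res$trace$status
  expect_identical(unname(st[c("a", "b", "c", "d", "e", "f", "g")]),
                   c("depth", "retained", "repeat_region", "vaf",
                     "read_end", "population_db", "normal_panel"))
  tr <- res$trace$counts
  expect_identical(res$trace$n_input,
                   sum(tr$removed) + tail(tr$retained_after, 1))
  expect_identical(nrow(res$retained), tail(tr$retained_after, 1))
  expect_error(filter_snvs(make_call(is_indel = TRUE,
                                     homopolymer_context = "AAA",
                                     anchor_pos = 1L)),
               class = "type_error")
  expect_error(filter_indels(make_call()), class = "type_error")
})

test_that("cascade terminal statuses equal an independent per-rule oracle", {
  snvs <- random_calls(1000, seed = 101)
  res <- filter_snvs(snvs)
  expect_identical(unname(res$trace$status), oracle_snv_status(snvs))
  indels <- random_calls(1000, seed = 102, indel = TRUE)
  resi <- filter_indels(indels)
  expect_identical(unname(resi$trace$status), oracle_indel_status(indels))
  # trace counts equal an independent tally of the oracle statuses
  tab <- table(factor(oracle_indel_status(indels),
                      levels = c(resi$trace$counts$rule, "retained")))
  expect_identical(unname(resi$trace$counts$removed),
                   as.integer(tab[resi$trace$counts$rule]))
})

test_that("filtering is idempotent and monotone in depth/VAF thresholds", {
  snvs <- random_calls(600, seed = 103)
  r1 <- filter_snvs(snvs)
  r2 <- filter_snvs(r1$retained)
  expect_identical(r2$retained, r1$retained)
  sizes <- outer(c(5, 10, 20, 40, 80), c(0.05, 0.1, 0.2, 0.4, 0.8),
                 Vectorize(function(d, v)
                   nrow(filter_snvs(snvs, filter_config(min_depth = d,
                                                        min_vaf = v))$retained)))
  expect_true(all(apply(sizes, 2, diff) <= 0))   # raising min_depth
  expect_true(all(apply(sizes, 1, diff) <= 0))   # raising min_vaf
})

test_that("protein-altering selection uses class term lists and drops chrM", {
  calls <- rbind(
    make_call(variant_id = "a", consequence_terms = "missense-variant"),
    make_call(variant_id = "b", consequence_terms = "synonymous-variant"),
    make_call(variant_id = "c", consequence_terms = "frameshift-variant",
              is_indel = TRUE, chrom = "chrM"),
    make_call(variant_id = "d", consequence_terms = "frameshift-variant",
              is_indel = TRUE),
    make_call(variant_id = "e", consequence_terms = "frameshift-variant",
              is_indel = FALSE),  # indel-only term on an SNV: not altering
    make_call(variant_id = "f",
              consequence_terms = "synonymous-variant;stop-gained"))
  out <- select_protein_altering(calls)
  expect_setequal(out$variant_id, c("a", "d", "f"))
  expect_warning(select_protein_altering(
    make_call(consequence_terms = "mystery-term")), "unknown consequence")
})

test_that("simulator defaults: drivers retained, germline removed", {
  b <- test_bundle()
  rna <- b$rna_variants
  res <- filter_snvs(rna[!rna$is_indel, ])
  pa <- select_protein_altering(res$retained)
  drivers <- rna$variant_id[rna$origin == "driver"]
  expect_true(all(drivers %in% pa$variant_id))
  germ <- rna$variant_id[rna$origin == "germline"]
  germ_exome <- b$exome_variants$variant_id[b$exome_variants$origin == "germline"]
  surviving <- sum(res$retained$variant_id %in% germ)
  expect_lt(surviving / length(germ_exome), 0.01)
})
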