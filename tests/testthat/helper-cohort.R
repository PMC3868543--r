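# Shared fixtures: one moderate-scale cohort bundle reused across test
# files (regenerating it per test would dominate runtime), plus a tiny
# hand-built variant table for cascade boundary checks.

.fixtures <- new.env(parent = emptyenv())

test_config <- function(...) {
  sim_config(n_patients = 31L, n_celllines = 18L, n_genes = 800L,
             germline_rate = 80, seed = 42L, ...)
}

test_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- simulate_cohort(test_config())
  .fixtures$bundle
}

test_norm <- function() {
  if (is.null(.fixtures$norm)) {
    b <- test_bundle()
    nm <- within_sample_normalize(b$count_matrix, "gc")
    nm <- within_sample_normalize(nm, "length")
    nm <- between_sample_normalize(nm, "upper_quartile")
    .fixtures$norm <- remove_batch_effect(nm)
  }
  .fixtures$norm
}

# one fully specified SNV row; override fields via ...
make_call <- function(..., variant_id = "V1", sample_id = "P01",
                      chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                      depth = 100L, vaf = 0.45, read_end_only = FALSE,
                      consequence_terms = "missense-variant",
                      gene_id = "NOTCH1", in_dbsnp = FALSE, in_1000g = FALSE,
                      in_cg = FALSE, in_normal_panel = FALSE,
                      in_thymus = FALSE, in_cosmic = FALSE,
                      in_repeat = FALSE, is_indel = FALSE,
                      homopolymer_context = NA_character_,
                      anchor_pos = NA_integer_, caller_pass = TRUE) {
  extra <- list(...)
  row <- data.frame(
    variant_id = variant_id, sample_id = sample_id, chrom = chrom, pos = pos,
    ref = ref, alt = alt, depth = depth,
    alt_depth = as.integer(round(vaf * depth)), vaf = vaf,
    read_end_only = read_end_only, consequence_terms = consequence_terms,
    gene_id = gene_id, in_dbsnp = in_dbsnp, in_1000g = in_1000g,
    in_cg = in_cg, in_normal_panel = in_normal_panel, in_thymus = in_thymus,
    in_cosmic = in_cosmic, in_repeat = in_repeat, is_indel = is_indel,
    homopolymer_context = homopolymer_context, anchor_pos = anchor_pos,
    caller_pass = caller_pass, origin = "test", stringsAsFactors = FALSE)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

make_calls <- function(n, ...) {
  rows <- lapply(seq_len(n), function(i) make_call(variant_id = sprintf("V%d", i)))
  df <- do.call(rbind, rows)
  args <- list(...)
  for (nm in names(args)) df[[nm]] <- args[[nm]]
  df
}

# independent per-rule brute force: first failing rule in cascade order,
# written rule-by-rule without the package's cascade machinery
oracle_snv_status <- function(calls, cfg = filter_config()) {
  vapply(seq_len(nrow(calls)), function(i) {
    v <- calls[i, ]
    if (v$read_end_only) return("read_end")
    if (v$depth < cfg$min_depth) return("depth")
    if (v$vaf < cfg$min_vaf) return("vaf")
    db <- v$in_dbsnp || v$in_1000g || v$in_cg
    if (db && !(cfg$cosmic_rescue && v$in_cosmic)) return("population_db")
    if (v$in_repeat) return("repeat_region")
    if (v$in_normal_panel || v$in_thymus) return("normal_panel")
    "retained"
  }, character(1))
}

oracle_indel_status <- function(calls, cfg = filter_config()) {
  vapply(seq_len(nrow(calls)), function(i) {
    v <- calls[i, ]
    if (!v$caller_pass) return("caller_quality")
    if (homopolymer_run_length(v$homopolymer_context, v$anchor_pos) >
        cfg$max_homopolymer) return("homopolymer")
    db <- v$in_dbsnp || v$in_1000g || v$in_cg
    if (db && !(cfg$cosmic_rescue && v$in_cosmic)) return("population_db")
    if (v$in_repeat) return("repeat_region")
    if (v$in_normal_panel || v$in_thymus) return("normal_panel")
    "retained"
  }, character(1))
}

# random variant tables exercising every rule, for oracle-equivalence tests
random_calls <- function(n, seed, indel = FALSE) {
  withr::with_seed(seed, {
    df <- make_calls(n)
    df$depth <- sample(5:120, n, replace = TRUE)
    df$vaf <- round(runif(n), 3)
    df$alt_depth <- as.integer(round(df$vaf * df$depth))
    df$vaf <- df$alt_depth / df$depth
    df$read_end_only <- runif(n) < 0.1
    df$in_dbsnp <- runif(n) < 0.3
    df$in_1000g <- runif(n) < 0.2
    df$in_cg <- runif(n) < 0.1
    df$in_cosmic <- runif(n) < 0.15
    df$in_repeat <- runif(n) < 0.1
    df$in_normal_panel <- runif(n) < 0.1
    df$in_thymus <- runif(n) < 0.1
    if (indel) {
      df$is_indel <- TRUE
      df$caller_pass <- runif(n) < 0.9
      runlen <- sample(1:9, n, replace = TRUE)
      df$homopolymer_context <- paste0("GC", strrep("A", runlen), "TG")
      df$anchor_pos <- 3L
    }
    df
  })
}
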