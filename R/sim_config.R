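#' Simulation configuration for a synthetic T-ALL cohort
#'
#' Builds and validates the configuration consumed by [simulate_cohort()]
#' and its component generators.  Defaults emulate the cohort the workflow
#' was designed for: 31 patients, 18 cell lines and one normal thymus
#' sample, six transcription-factor-defined subtypes, two collection
#' centers, negative-binomial counts with GC and length bias, planted
#' recurrent drivers, germline SNPs with database memberships, a small
#' allelically imbalanced fraction, true fusions of the three consequence
#' classes plus read-through/ribosomal/mitochondrial decoys, and
#' exon-skipping events at fixed true PSI.
#'
#' @param n_patients Number of patient samples (default 31).
#' @param n_celllines Number of cell-line samples (default 18).
#' @param include_thymus Include one normal thymus control (default TRUE).
#' @param n_genes Number of genes in the simulated annotation (default 2000).
#' @param n_ribosomal Number of ribosomal-flagged genes (default 20).
#' @param n_driver_genes Number of planted driver genes, seeded from the
#'   curated 47-gene T-ALL list (default 12; at most 47).
#' @param driver_recurrence Expected number of mutated patients per driver
#'   gene (default 4; every driver is planted in at least 2 patients).
#' @param germline_rate Expected germline SNPs per sample (default 120).
#' @param passenger_rate Expected somatic passenger variants per sample
#'   (default 8).
#' @param artifact_rate Expected artifact calls (read-end / repeat-region /
#'   thymus-shared) per sample (default 12).
#' @param cosmic_overlap_rate Fraction of driver variants that are also in
#'   population databases but carry COSMIC membership (default 0.1).
#' @param allelic_imbalance_fraction Fraction of DNA-het sites expressed
#'   mono-allelically (RNA hom-var); default 0.035.
#' @param rna_het_rate Fraction of covered DNA-het sites re-emitted as RNA
#'   het calls (default 0.72); the remainder after adding
#'   `allelic_imbalance_fraction` is reference-only dropout.
#' @param mean_depth Mean sequencing depth at a variant site in a gene of
#'   average expression (default 60 reads).
#' @param n_batches Number of collection centers (default 2).
#' @param batch_effect_sd Per-gene, per-center log2 shift SD (default 0.5).
#' @param subtype_programs Named list mapping each subtype-defining TF to
#'   `list(tf_lfc=, n_targets=, target_lfc=)`; defaults boost the TF by
#'   +4 log2 and 30 co-regulated target genes by +2 log2 in assigned samples.
#' @param nb_dispersion Negative-binomial dispersion (default 0.2).
#' @param gc_bias_slope Amplitude of the smooth quadratic GC trend on the
#'   log2 mean (default 1).
#' @param length_bias_exponent Power-law exponent of counts on exonic
#'   length (default 1: counts proportional to length).
#' @param n_true_fusions,n_decoy_fusions Planted true fusions and decoys
#'   (defaults 6 and 12).
#' @param skipping_events Data frame with columns `gene`, `sample_index`
#'   (patient index), `psi`, `depth`; `NULL` gives two default events
#'   emulating canonical-exon skipping at PSI 0.35 (depth 400) and 0.40
#'   (depth 300).
#' @param seed Default seed recorded in the config (individual generators
#'   also take an explicit seed).
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_patients = 31L, n_celllines = 18L,
                       include_thymus = TRUE,
                       n_genes = 2000L, n_ribosomal = 20L,
                       n_driver_genes = 12L, driver_recurrence = 4,
                       germline_rate = 120, passenger_rate = 8,
                       artifact_rate = 12,
                       cosmic_overlap_rate = 0.1,
                       allelic_imbalance_fraction = 0.035,
                       rna_het_rate = 0.72,
                       mean_depth = 60,
                       n_batches = 2L, batch_effect_sd = 0.5,
                       subtype_programs = NULL,
                       nb_dispersion = 0.2,
                       gc_bias_slope = 1, length_bias_exponent = 1,
                       n_true_fusions = 6L, n_decoy_fusions = 12L,
                       skipping_events = NULL,
                       seed = 1L) {
  if (is.null(subtype_programs)) {
    subtype_programs <- setNames(
      rep(list(list(tf_lfc = 4, n_targets = 30L, target_lfc = 2)),
          length(tall_subtype_tfs)),
      tall_subtype_tfs)
  }
  if (is.null(skipping_events)) {
    skipping_events <- data.frame(
      gene = c("SUZ12", "LCK"),
      sample_index = c(5L, 5L),
      psi = c(0.35, 0.40),
      depth = c(400L, 300L),
      stringsAsFactors = FALSE)
  }
  cfg <- list(
    n_patients = as.integer(n_patients), n_celllines = as.integer(n_celllines),
    include_thymus = isTRUE(include_thymus),
    n_genes = as.integer(n_genes), n_ribosomal = as.integer(n_ribosomal),
    n_driver_genes = as.integer(n_driver_genes),
    driver_recurrence = driver_recurrence,
    germline_rate = germline_rate, passenger_rate = passenger_rate,
    artifact_rate = artifact_rate,
    cosmic_overlap_rate = cosmic_overlap_rate,
    allelic_imbalance_fraction = allelic_imbalance_fraction,
    rna_het_rate = rna_het_rate,
    mean_depth = mean_depth,
    n_batches = as.integer(n_batches), batch_effect_sd = batch_effect_sd,
    subtype_programs = subtype_programs,
    nb_dispersion = nb_dispersion,
    gc_bias_slope = gc_bias_slope,
    length_bias_exponent = length_bias_exponent,
    n_true_fusions = as.integer(n_true_fusions),
    n_decoy_fusions = as.integer(n_decoy_fusions),
    skipping_events = skipping_events,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_patients", "n_celllines", "n_genes", "n_ribosomal",
              "n_driver_genes", "n_batches", "n_true_fusions",
              "n_decoy_fusions")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      abort(sprintf("'%s' must be a non-negative count", f), "config_error")
  }
  if (cfg$n_patients < 1)
    abort("'n_patients' must be positive", "config_error")
  if (cfg$n_genes < 10)
    abort("'n_genes' must be at least 10", "config_error")
  fracs <- c("cosmic_overlap_rate", "allelic_imbalance_fraction",
             "rna_het_rate")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      abort(sprintf("'%s' must lie in [0,1]", f), "config_error")
  }
  if (cfg$allelic_imbalance_fraction + cfg$rna_het_rate > 1)
    abort("rna_het_rate + allelic_imbalance_fraction must be <= 1",
          "config_error")
  if (cfg$nb_dispersion <= 0)
    abort("'nb_dispersion' must be > 0", "config_error")
  if (cfg$batch_effect_sd > 0 && cfg$n_batches < 2)
    abort("batch_effect_sd > 0 requires at least 2 batches", "config_error")
  if (cfg$n_driver_genes > length(tall_driver_genes))
    abort("n_driver_genes exceeds the curated driver list", "config_error")
  invisible(cfg)
}
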