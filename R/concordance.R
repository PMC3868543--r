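# RNA-seq versus exome concordance: shared/exclusive calls at >=20x in
# both assays, VAF scatter pairs, and the allelic-imbalance breakdown of
# DNA-heterozygous sites.

site_key <- function(df) paste(df$sample_id, df$chrom, df$pos, sep = ":")

#' Compare an exome callset with an RNA-seq callset
#'
#' Sites are categorized as called in both assays, exome-only or RNA-only,
#' restricted to positions with at least `min_depth` coverage in both
#' assays (strictly greater when `strict = TRUE`).  Recall is reported both
#' conditioned on RNA coverage at the exome site and unconditioned over all
#' exome calls.
#'
#' @param exome_calls,rna_calls Variant tables with `sample_id`, `chrom`,
#'   `pos`, `vaf`.
#' @param coverage Data frame with `sample_id`, `chrom`, `pos`,
#'   `exome_depth`, `rna_depth` giving per-site depth in both assays.
#' @param min_depth Coverage threshold (default 20).
#' @param strict Use strictly-greater instead of at-least (default FALSE).
#' @return A `concordance_report` list: `n_both`, `n_exome_only`,
#'   `n_rna_only`, `recall` (coverage-conditioned), `recall_unconditioned`,
#'   and `vaf_pairs` (data frame of shared-site VAFs for the scatter plot).
#' @export
compare_callsets <- function(exome_calls, rna_calls, coverage,
                             min_depth = 20L, strict = FALSE) {
  samples_e <- unique(exome_calls$sample_id)
  samples_r <- unique(rna_calls$sample_id)
  if (length(setdiff(samples_r, c(samples_e, unique(coverage$sample_id)))) &&
      length(samples_e))
    abort("RNA calls carry samples absent from the exome/coverage tables",
          "pairing_error")
  pass <- function(d) if (strict) d > min_depth else d >= min_depth
  cov_ok <- pass(coverage$exome_depth) & pass(coverage$rna_depth)
  ok_keys <- site_key(coverage)[cov_ok]
  ek <- site_key(exome_calls); rk <- site_key(rna_calls)
  e_ok <- ek[ek %in% ok_keys]; r_ok <- rk[rk %in% ok_keys]
  both <- intersect(e_ok, r_ok)
  report <- list(
    n_both = length(both),
    n_exome_only = length(setdiff(e_ok, r_ok)),
    n_rna_only = length(setdiff(r_ok, e_ok)),
    recall = if (length(e_ok)) length(both) / length(e_ok) else NA_real_,
    recall_unconditioned = if (length(ek))
      length(intersect(ek, rk)) / length(ek) else NA_real_,
    min_depth = min_depth, strict = strict)
  shared_e <- exome_calls[ek %in% both, c("sample_id", "chrom", "pos", "vaf")]
  names(shared_e)[4] <- "vaf_exome"
  shared_r <- rna_calls[rk %in% both, c("sample_id", "chrom", "pos", "vaf")]
  names(shared_r)[4] <- "vaf_rna"
  report$vaf_pairs <- merge(shared_e, shared_r,
                            by = c("sample_id", "chrom", "pos"))
  structure(report, class = "concordance_report")
}

#' Allelic-imbalance breakdown of DNA-heterozygous sites
#'
#' Each DNA-het site is classed from the RNA table via [classify_genotype()];
#' a site with adequate RNA coverage but no RNA call is `hom_ref`
#' (reference only — the variant allele is not expressed or dropped out),
#' and a site with RNA coverage below `min_depth` is excluded from the
#' breakdown.  `hom_var` sites are the mono-allelically expressed
#' (allelically imbalanced) fraction.
#'
#' @param dna_het_sites Exome table restricted to heterozygous calls.
#' @param rna_calls RNA variant table.
#' @param coverage Per-site depth table as in [compare_callsets()].
#' @param min_depth RNA coverage required to class a site (default 20).
#' @param thresholds Genotype VAF bins passed to [classify_genotype()].
#' @return A `het_breakdown` list: integer `counts` (het, hom_ref, hom_var),
#'   `n_total`, `fractions` (raw), and `printed` (het as integer percent,
#'   hom_var to one decimal — the reporting precision of the analysis).
#' @export
allelic_imbalance_breakdown <- function(dna_het_sites, rna_calls, coverage,
                                        min_depth = 20L,
                                        thresholds = c(het_min = 0.2,
                                                       hom_min = 0.8)) {
  ck <- site_key(coverage)
  dk <- site_key(dna_het_sites)
  rna_cov <- coverage$rna_depth[match(dk, ck)]
  missing_cov <- is.na(rna_cov)
  if (any(missing_cov))
    warning(sum(missing_cov), " site(s) without RNA coverage info counted hom_ref")
  rna_cov[missing_cov] <- 0L
  usable <- missing_cov | rna_cov >= min_depth
  dk_use <- dk[usable]
  rk <- site_key(rna_calls)
  hit <- match(dk_use, rk)
  class <- rep("hom_ref", length(dk_use))
  called <- !is.na(hit)
  if (any(called))
    class[called] <- classify_genotype(rna_calls$vaf[hit[called]],
                                       rna_calls$depth[hit[called]],
                                       thresholds)
  counts <- c(het = sum(class == "het"),
              hom_ref = sum(class == "hom_ref"),
              hom_var = sum(class == "hom_var"))
  n <- length(dk_use)
  structure(list(
    counts = counts, n_total = n,
    fractions = counts / n,
    printed = c(het_pct = round(100 * counts[["het"]] / n),
                hom_var_pct = round(100 * counts[["hom_var"]] / n, 1),
                hom_ref_n = counts[["hom_ref"]]),
    n_excluded_low_coverage = sum(!usable)),
    class = "het_breakdown")
}
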