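# SNV/INDEL filter cascade: read-end artifacts, depth/VAF thresholds,
# population-database subtraction with COSMIC rescue, repeat regions,
# normal-panel/thymus subtraction, homopolymer INDEL filter, and
# protein-altering consequence selection.

#' Filter configuration for the variant cascade
#'
#' @param min_depth Minimum depth of coverage (default 20).
#' @param min_vaf Minimum variant allele frequency (default 0.20).
#' @param max_homopolymer INDELs in homopolymer runs strictly longer than
#'   this are removed (default 5).
#' @param cosmic_rescue Retain population-database variants that are also in
#'   COSMIC (default TRUE).  The rescue is scoped to the SNP databases
#'   (dbSNP / 1000 Genomes / Complete Genomics) only; repeat,
#'   normal-panel and thymus filters are never rescued.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 20L, min_vaf = 0.20,
                          max_homopolymer = 5L, cosmic_rescue = TRUE) {
  if (min_depth < 1) abort("min_depth must be >= 1", "config_error")
  if (min_vaf <= 0 || min_vaf > 1) abort("min_vaf must be in (0,1]",
                                         "config_error")
  structure(list(min_depth = as.integer(min_depth), min_vaf = min_vaf,
                 max_homopolymer = as.integer(max_homopolymer),
                 cosmic_rescue = isTRUE(cosmic_rescue),
                 protein_altering_terms_snv = protein_altering_terms("snv"),
                 protein_altering_terms_indel = protein_altering_terms("indel")),
            class = "filter_config")
}

#' Classify a genotype from VAF bins
#'
#' Deterministic genotype call from the variant allele frequency:
#' `hom_ref` below `het_min`, `het` in `[het_min, hom_min)`, `hom_var` at or
#' above `hom_min`.
#'
#' @param vaf Numeric vector in [0,1].
#' @param depth Read depth(s); must be >= 1.
#' @param thresholds Named numeric, `c(het_min = 0.2, hom_min = 0.8)`.
#' @return Character vector in `{hom_ref, het, hom_var}`.
#' @export
classify_genotype <- function(vaf, depth,
                              thresholds = c(het_min = 0.2, hom_min = 0.8)) {
  if (any(depth < 1)) abort("genotype undefined at depth 0", "genotype_error")
  stopifnot(all(vaf >= 0 & vaf <= 1))
  ifelse(vaf >= thresholds[["hom_min"]], "hom_var",
         ifelse(vaf >= thresholds[["het_min"]], "het", "hom_ref"))
}

#' Longest homopolymer run touching an INDEL anchor
#'
#' Scans the flanking sequence for single-nucleotide runs and returns the
#' length of the longest run that touches (overlaps or is immediately
#' adjacent to) the anchor position of the INDEL.
#'
#' @param context Nucleotide string (A/C/G/T/N).
#' @param indel_position 1-based anchor position within `context`.
#' @return Integer run length in bp.
#' @export
homopolymer_run_length <- function(context, indel_position) {
  if (!nzchar(context) || is.na(context))
    abort("empty homopolymer context", "format_error")
  chars <- strsplit(toupper(context), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    abort("non-ACGTN character in homopolymer context", "format_error")
  if (indel_position < 1 || indel_position > length(chars))
    abort("indel anchor outside context", "format_error")
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  touching <- starts <= indel_position + 1L & ends >= indel_position - 1L
  max(r$lengths[touching])
}

# one cascade rule: returns logical "fails"
.rule_fails <- function(calls, rule, config) {
  switch(rule,
    caller_quality = !calls$caller_pass,
    read_end = calls$read_end_only,
    depth = calls$depth < config$min_depth,
    vaf = calls$vaf < config$min_vaf,
    homopolymer = vapply(seq_len(nrow(calls)), function(i)
      homopolymer_run_length(calls$homopolymer_context[i],
                             calls$anchor_pos[i]) > config$max_homopolymer,
      logical(1)),
    population_db = {
      in_db <- calls$in_dbsnp | calls$in_1000g | calls$in_cg
      if (config$cosmic_rescue) in_db & !calls$in_cosmic else in_db
    },
    repeat_region = calls$in_repeat,
    normal_panel = calls$in_normal_panel | calls$in_thymus,
    abort(paste("unknown rule", rule), "config_error"))
}

.apply_cascade <- function(calls, rules, config) {
  status <- rep("retained", nrow(calls))
  trace <- data.frame(rule = rules, removed = 0L, retained_after = 0L,
                      stringsAsFactors = FALSE)
  alive <- rep(TRUE, nrow(calls))
  for (k in seq_along(rules)) {
    fails <- alive & .rule_fails(calls, rules[k], config)
    status[fails] <- rules[k]
    alive <- alive & !fails
    trace$removed[k] <- sum(fails)
    trace$retained_after[k] <- sum(alive)
  }
  list(retained = calls[alive, , drop = FALSE],
       trace = structure(list(counts = trace,
                              status = setNames(status, calls$variant_id),
                              n_input = nrow(calls)),
                         class = "filter_trace"))
}

#' Filter SNV calls through the fixed cascade
#'
#' Cascade order: read-end artifact, depth of coverage, variant allele
#' frequency, population-database subtraction (with COSMIC rescue), repeat
#' regions, normal-panel/thymus subtraction.  Each variant receives exactly
#' one terminal status (the first failing rule, or `retained`), and the
#' per-rule counts telescope.
#'
#' @param calls VariantCall data frame (SNVs only; see
#'   [simulate_variant_tables()] for the columns).
#' @param config A [filter_config()].
#' @return List with `retained` (data frame) and `trace` (`filter_trace`:
#'   `$counts`, per-variant `$status`, `$n_input`).
#' @export
filter_snvs <- function(calls, config = filter_config()) {
  if (any(calls$is_indel))
    abort("INDEL passed to the SNV filter path", "type_error")
  .apply_cascade(calls,
                 c("read_end", "depth", "vaf", "population_db",
                   "repeat_region", "normal_panel"),
                 config)
}

#' Filter INDEL calls
#'
#' INDELs carry an upstream caller-quality flag (honored as an input
#' attribute), are removed when located in homopolymer runs strictly longer
#' than `max_homopolymer` bp touching the INDEL anchor, and then pass
#' through the shared database / repeat / normal-panel cascade.
#'
#' @inheritParams filter_snvs
#' @return Same structure as [filter_snvs()].
#' @export
filter_indels <- function(calls, config = filter_config()) {
  if (any(!calls$is_indel))
    abort("SNV passed to the INDEL filter path", "type_error")
  if (any(is.na(calls$homopolymer_context) | !nzchar(calls$homopolymer_context)))
    abort("INDEL without homopolymer context", "format_error")
  .apply_cascade(calls,
                 c("caller_quality", "homopolymer", "population_db",
                   "repeat_region", "normal_panel"),
                 config)
}

#' Select protein-altering variants
#'
#' Keeps calls whose consequence terms intersect the class-appropriate
#' protein-altering list (SNV or INDEL term set), and removes mitochondrial
#' (chrM) variants.  Unknown consequence terms raise a warning and count as
#' non-altering.
#'
#' @param calls VariantCall data frame with `consequence_terms`
#'   (`;`-separated), `is_indel` and `chrom`.
#' @param config A [filter_config()].
#' @return The protein-altering subset of `calls`.
#' @export
select_protein_altering <- function(calls, config = filter_config()) {
  if (nrow(calls) == 0) return(calls)
  terms <- strsplit(calls$consequence_terms, ";", fixed = TRUE)
  if (any(lengths(terms) == 0))
    abort("call without consequence terms", "format_error")
  known <- c(protein_altering_terms("indel"), known_benign_terms)
  unknown <- setdiff(unique(unlist(terms)), known)
  if (length(unknown))
    warning("unknown consequence term(s) treated as non-altering: ",
            paste(unknown, collapse = ", "))
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    lst <- if (calls$is_indel[i]) config$protein_altering_terms_indel
           else config$protein_altering_terms_snv
    any(terms[[i]] %in% lst)
  }, logical(1))
  keep <- keep & calls$chrom != "chrM"
  calls[keep, , drop = FALSE]
}
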