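# Orchestrator: simulate -> filter -> concordance -> recurrence ->
# normalize -> co-expression/GSEA -> fusions -> splice scan, with a JSON
# run manifest.  One master seed fans out to per-stage child seeds via
# stage_seed(), so any stage can be replayed in isolation.

#' Run the full pipeline on a simulated cohort
#'
#' Executes every stage in order on a cohort generated from `config`,
#' writes all stage outputs (VCF, GTF, TSV, JSON) under `outdir`, and
#' writes a run manifest last.  Identical `(config, seed)` reproduce every
#' output byte-identically (manifest timestamps aside).
#'
#' @param config A [sim_config()], or a path to a JSON file of config
#'   fields.
#' @param outdir Output directory (created if needed).
#' @param seed Master seed (default `config$seed`).
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) {
    fields <- jsonlite::read_json(config, simplifyVector = TRUE)
    fields <- fields[names(fields) %in% names(formals(sim_config))]
    config <- do.call(sim_config, fields)
  }
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "tallseq", version = "0.1.0", seed = seed,
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  note <- function(stage, files, rows) {
    manifest$stages[[stage]] <<- list(files = files, rows = rows,
                                      seed = stage_seed(seed, stage))
  }
  p <- function(...) file.path(outdir, ...)

  ## simulate
  bundle <- simulate_cohort(config, seed)
  write_gene_models_gtf(bundle$gene_models, p("gene_models.gtf"))
  write_counts_tsv(bundle$count_matrix$counts, p("counts.tsv"))
  write_tsv(bundle$sample_meta, p("sample_meta.tsv"))
  write_variants_vcf(bundle$exome_variants, p("exome_variants.vcf"))
  write_variants_vcf(bundle$rna_variants, p("rna_variants.vcf"))
  write_tsv(bundle$fusions, p("fusion_candidates.tsv"))
  write_tsv(bundle$junctions, p("junctions.tsv"))
  note("simulate",
       c("gene_models.gtf", "counts.tsv", "sample_meta.tsv",
         "exome_variants.vcf", "rna_variants.vcf",
         "fusion_candidates.tsv", "junctions.tsv"),
       c(nrow(bundle$gene_models), nrow(bundle$exome_variants),
         nrow(bundle$rna_variants), nrow(bundle$fusions),
         nrow(bundle$junctions)))

  ## variant triage on the RNA-seq calls
  fc <- filter_config()
  snv <- bundle$rna_variants[!bundle$rna_variants$is_indel, , drop = FALSE]
  ind <- bundle$rna_variants[bundle$rna_variants$is_indel, , drop = FALSE]
  fs <- filter_snvs(snv, fc)
  fi <- if (nrow(ind)) filter_indels(ind, fc) else
    list(retained = ind, trace = NULL)
  pa <- select_protein_altering(rbind(fs$retained, fi$retained), fc)
  write_variants_vcf(pa, p("protein_altering.vcf"))
  jsonlite::write_json(
    list(snv = fs$trace$counts,
         indel = if (!is.null(fi$trace)) fi$trace$counts else NULL),
    p("filter_trace.json"), auto_unbox = TRUE, digits = NA)
  note("filter_variants", c("protein_altering.vcf", "filter_trace.json"),
       nrow(pa))

  ## concordance (exome het sites vs RNA)
  het <- bundle$exome_variants[
    classify_genotype(bundle$exome_variants$vaf,
                      bundle$exome_variants$depth) == "het", , drop = FALSE]
  conc <- compare_callsets(bundle$exome_variants, bundle$rna_variants,
                           bundle$coverage)
  brk <- allelic_imbalance_breakdown(het, bundle$rna_variants,
                                     bundle$coverage)
  jsonlite::write_json(
    list(n_both = conc$n_both, n_exome_only = conc$n_exome_only,
         n_rna_only = conc$n_rna_only, recall = conc$recall,
         recall_unconditioned = conc$recall_unconditioned,
         het_breakdown = as.list(brk$counts)),
    p("concordance.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(conc$vaf_pairs, p("vaf_scatter.tsv"))
  note("concordance", c("concordance.json", "vaf_scatter.tsv"), conc$n_both)

  ## recurrence
  rec <- select_recurrent_genes(pa, bundle$sample_meta)
  rec_tab <- data.frame(
    gene_id = names(rec$gene_patients),
    n_patients = vapply(rec$gene_patients, length, integer(1)),
    selected = names(rec$gene_patients) %in% rec$selected)
  write_tsv(rec_tab[order(-rec_tab$n_patients), ], p("recurrence.tsv"))
  write_tsv(data.frame(sample_id = names(rec$per_sample_counts),
                       n_protein_altering = rec$per_sample_counts),
            p("burden.tsv"))
  note("recurrence", c("recurrence.tsv", "burden.tsv"),
       length(rec$selected))

  ## normalization + clustering
  nmx <- within_sample_normalize(bundle$count_matrix, "gc")
  nmx <- within_sample_normalize(nmx, "length")
  nmx <- between_sample_normalize(nmx, "upper_quartile")
  nmx <- remove_batch_effect(nmx)
  write_counts_tsv(round(nmx$values, 4), p("normalized_log2.tsv"))
  tfs <- intersect(tall_subtype_tfs, rownames(nmx$values))
  clusters <- cluster_subtypes(nmx, tf_list = tfs,
                               k = min(6L, ncol(nmx$values) - 1L))
  write_tsv(data.frame(sample_id = names(clusters), cluster = clusters),
            p("subtype_clusters.tsv"))
  jsonlite::write_json(as.list(nmx$provenance), p("normalization_provenance.json"),
                       auto_unbox = TRUE)
  note("normalize", c("normalized_log2.tsv", "subtype_clusters.tsv",
                      "normalization_provenance.json"),
       nrow(nmx$values))

  ## co-expression + GSEA on the first subtype TF
  tf <- tfs[1]
  coexpr <- ptm_neighbors(nmx, tf, p_threshold = 1e-5)
  write_tsv(coexpr, p("ptm_neighbors.tsv"))
  sig <- bundle$truth$subtype_signatures[[tf]]
  gsea <- if (!is.null(sig) && length(sig) >= 5) {
    ranking <- rank_by_group_lfc(nmx, marker_gene = tf)
    gsea_enrichment(ranking, sig, n_perm = 500L,
                    seed = stage_seed(seed, "gsea"))
  } else NULL
  if (!is.null(gsea))
    jsonlite::write_json(list(tf = tf, es = gsea$es, p_value = gsea$p_value),
                         p("gsea.json"), auto_unbox = TRUE, digits = NA)
  note("coexpression", c("ptm_neighbors.tsv", "gsea.json"), nrow(coexpr))

  ## fusion triage
  fus <- triage_fusions(bundle$fusions, bundle$gene_models, nmx,
                        thymus_sample = if (config$include_thymus) "THYMUS"
                        else colnames(nmx$values)[1])
  write_tsv(fus, p("fusion_calls.tsv"))
  note("fusions", "fusion_calls.tsv", sum(fus$retained))

  ## splice scan
  spl <- scan_events(bundle$junctions,
                     control_sample = if (config$include_thymus) "THYMUS"
                     else bundle$sample_meta$sample_id[1])
  write_tsv(spl, p("splice_scan.tsv"))
  note("splice", "splice_scan.tsv", sum(spl$significant))

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `run-all --config cfg.json --seed N --outdir D` (the full
#' pipeline) and `simulate` (cohort outputs only).  Intended for
#' `Rscript -e 'tallseq::tallseq_main()' run-all --outdir out`.
#'
#' @param args Character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return Exit status, invisibly.
#' @export
tallseq_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: tallseq <run-all|simulate> [--config cfg.json] ",
            "[--seed N] [--outdir D]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  outdir <- opt("--outdir", "tallseq_out")
  seed <- as.integer(opt("--seed", "1"))
  cfgpath <- opt("--config", NA)
  config <- if (!is.na(cfgpath)) cfgpath else sim_config(seed = seed)
  if (cmd %in% c("run-all", "simulate")) {
    run_pipeline(config, outdir, seed = seed)
    invisible(0L)
  } else {
    message("unknown subcommand: ", cmd)
    invisible(1L)
  }
}
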