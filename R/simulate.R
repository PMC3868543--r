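# Cohort simulator: synthetic T-ALL cohorts with planted drivers, batch
# shifts, subtype programs, fusions and exon-skipping events.  Every
# generator is a pure function of (config, seed): the global RNG state is
# saved and restored around each call.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% (2^31 - 1)))
  force(code)
}

#' Simulate a gene annotation
#'
#' Lays `n_genes` genes contiguously and non-overlappingly on four autosomal
#' contigs plus a mitochondrial contig (`chrM`), so that genomic neighbor
#' order is unambiguous.  A curated set of real T-ALL gene symbols (drivers,
#' subtype transcription factors, tumor suppressors) is embedded in the
#' universe; a configured number of genes is flagged ribosomal.  GC
#' fractions lie in [0.2, 0.8] and exonic lengths follow a log-normal law.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `data.frame` (class `gene_models`) with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `n_exons`, `exonic_length`, `gc`,
#'   `is_ribosomal`, `is_chrM`, `is_driver`, `is_tsg`, `is_tf`,
#'   `neighbor_rank` (1-based rank by start within chromosome).
#' @export
simulate_gene_models <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n <- config$n_genes
  with_seed(seed, {
    n_mito <- max(2L, min(10L, as.integer(round(n * 0.01))))
    named <- unique(c(tall_driver_genes, tall_subtype_tfs, "TP53", "IKZF1"))
    n_named <- min(length(named), max(0L, n - n_mito - config$n_ribosomal))
    named <- head(named, n_named)
    n_ribo <- min(config$n_ribosomal, n - n_mito - n_named)
    ids <- c(named,
             if (n_ribo > 0) sprintf("RIBO%03d", seq_len(n_ribo)),
             sprintf("G%05d", seq_len(n - n_named - n_ribo - n_mito)),
             sprintf("MT-G%02d", seq_len(n_mito)))
    is_mito <- c(rep(FALSE, n - n_mito), rep(TRUE, n_mito))
    is_ribo <- grepl("^RIBO", ids)
    # shuffle nuclear genes over 4 chromosomes; chrM genes stay on chrM
    nuc <- which(!is_mito)
    chrom <- character(n)
    chrom[is_mito] <- "chrM"
    chrom[nuc] <- paste0("chr", sample(1:4, length(nuc), replace = TRUE))
    exonic_length <- pmax(200L, pmin(20000L,
      as.integer(round(rlnorm(n, log(1500), 0.7)))))
    n_exons <- pmax(2L, rpois(n, 7) + 1L)
    gc <- runif(n, 0.2, 0.8)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gm <- data.frame(
      gene_id = ids, chrom = chrom, start = 0L, end = 0L, strand = strand,
      n_exons = n_exons, exonic_length = exonic_length, gc = gc,
      is_ribosomal = is_ribo, is_chrM = is_mito,
      is_driver = ids %in% tall_driver_genes,
      is_tsg = ids %in% tall_tumor_suppressors,
      is_tf = ids %in% tall_subtype_tfs,
      neighbor_rank = NA_integer_, stringsAsFactors = FALSE)
    # contiguous, non-overlapping layout per chromosome (1-based closed)
    for (ch in unique(gm$chrom)) {
      idx <- which(gm$chrom == ch)
      idx <- idx[sample.int(length(idx))]          # random gene order on chrom
      span <- as.integer(round(gm$exonic_length[idx] * runif(length(idx), 2, 8)))
      gap <- as.integer(round(runif(length(idx), 1e3, 5e4)))
      starts <- cumsum(c(1L, head(span + gap, -1L)))
      gm$start[idx] <- starts
      gm$end[idx] <- starts + span - 1L
      gm$neighbor_rank[idx] <- seq_along(idx)
    }
    class(gm) <- c("gene_models", "data.frame")
    gm
  })
}

# deterministic sample sheet: ids, types, batches, subtype assignment
simulate_sample_meta <- function(config) {
  validate_sim_config(config)
  ids <- c(sprintf("P%02d", seq_len(config$n_patients)),
           sprintf("CL%02d", seq_len(config$n_celllines)),
           if (config$include_thymus) "THYMUS")
  type <- c(rep("patient", config$n_patients),
            rep("cell_line", config$n_celllines),
            if (config$include_thymus) "thymus")
  tumor <- type != "thymus"
  # blocked center assignment: crossing the round-robin subtype cycle with
  # blocks keeps subtype and center unconfounded
  batch <- rep(paste0("center", seq_len(config$n_batches)),
               each = ceiling(length(ids) / config$n_batches))[seq_along(ids)]
  tfs <- names(config$subtype_programs)
  subtype <- rep(NA_character_, length(ids))
  subtype[tumor] <- rep_len(tfs, sum(tumor))
  cohort <- rep(NA_character_, length(ids))
  cohort[type == "patient"] <-
    rep_len(c("adult", "pediatric"), config$n_patients)
  data.frame(sample_id = ids, sample_type = type, center = batch,
             subtype = subtype, cohort = cohort, stringsAsFactors = FALSE)
}

#' Simulate a gene-by-sample count matrix
#'
#' Counts are negative binomial with mean
#' `base * length^e * exp(gc trend) * 2^(batch shift) * 2^(subtype boost)`.
#' The GC trend is a smooth quadratic hump on the log mean (amplitude
#' `gc_bias_slope`), length bias is a power law, batch shifts are per
#' gene-by-center Gaussian log2 shifts, and each subtype program boosts its
#' transcription factor and a disjoint set of co-regulated target genes in
#' assigned samples.  Driver and TF genes get a floor on baseline
#' expression (they are expressed in T-ALL).
#'
#' @param config A [sim_config()].
#' @param gene_models From [simulate_gene_models()].
#' @param seed Integer seed.
#' @param sample_meta Optional precomputed sample sheet.
#' @return A `count_matrix`: list with `counts` (integer matrix, genes x
#'   samples), `gene_annot`, `sample_meta`, and `truth` (batch shift matrix,
#'   subtype signatures, base means).
#' @export
simulate_counts <- function(config, gene_models, seed = config$seed,
                            sample_meta = NULL) {
  validate_sim_config(config)
  if (is.null(sample_meta)) sample_meta <- simulate_sample_meta(config)
  if (config$batch_effect_sd > 0 &&
      length(unique(sample_meta$center)) < 2)
    abort("batch effects require >= 2 centers", "config_error")
  with_seed(seed, {
    n <- nrow(gene_models); m <- nrow(sample_meta)
    base <- rlnorm(n, log(60), 1.2)
    base[gene_models$is_driver | gene_models$is_tf] <-
      pmax(base[gene_models$is_driver | gene_models$is_tf], 60)
    len_fac <- (gene_models$exonic_length /
                  median(gene_models$exonic_length))^config$length_bias_exponent
    gc_fac <- exp(config$gc_bias_slope *
                    (1 - ((gene_models$gc - 0.5) / 0.3)^2))
    centers <- sort(unique(sample_meta$center))
    shifts <- matrix(rnorm(n * length(centers), 0, config$batch_effect_sd),
                     n, length(centers), dimnames = list(gene_models$gene_id,
                                                         centers))
    if (config$batch_effect_sd == 0) shifts[] <- 0
    # disjoint target signatures per subtype TF
    tfs <- names(config$subtype_programs)
    pool <- setdiff(gene_models$gene_id[!gene_models$is_driver &
                                          !gene_models$is_tf &
                                          !gene_models$is_ribosomal &
                                          !gene_models$is_chrM], tfs)
    signatures <- list()
    for (tf in tfs) {
      k <- min(config$subtype_programs[[tf]]$n_targets, length(pool))
      signatures[[tf]] <- sample(pool, k)
      pool <- setdiff(pool, signatures[[tf]])
    }
    mu <- matrix(base * len_fac * gc_fac, n, m,
                 dimnames = list(gene_models$gene_id, sample_meta$sample_id))
    for (j in seq_len(m)) {
      mu[, j] <- mu[, j] * 2^shifts[, match(sample_meta$center[j], centers)]
      st <- sample_meta$subtype[j]
      if (!is.na(st) && st %in% tfs) {
        prog <- config$subtype_programs[[st]]
        if (st %in% rownames(mu))
          mu[st, j] <- mu[st, j] * 2^prog$tf_lfc
        sig <- signatures[[st]]
        mu[sig, j] <- mu[sig, j] * 2^prog$target_lfc
      }
    }
    counts <- matrix(as.integer(rnbinom(n * m, mu = mu,
                                        size = 1 / config$nb_dispersion)),
                     n, m, dimnames = dimnames(mu))
    structure(list(counts = counts, gene_annot = gene_models,
                   sample_meta = sample_meta,
                   truth = list(batch_shifts = shifts,
                                subtype_signatures = signatures,
                                base_mean = setNames(base,
                                                     gene_models$gene_id))),
              class = "count_matrix")
  })
}

# nearest downstream neighbor (next neighbor_rank on same chromosome), or NA
downstream_neighbor <- function(gene_models, gene_id) {
  i <- match(gene_id, gene_models$gene_id)
  hit <- which(gene_models$chrom == gene_models$chrom[i] &
                 gene_models$neighbor_rank == gene_models$neighbor_rank[i] + 1L)
  if (length(hit)) gene_models$gene_id[hit[1]] else NA_character_
}

#' Simulate fusion candidates and junction tables
#'
#' Plants `n_true_fusions` cycling through the three consequence classes —
#' in-frame chimeric-protein fusions between coding genes, out-of-frame
#' fusions whose partner (or its nearest downstream neighbor) is strongly
#' over-expressed in the carrier sample, and fusions suppressing a
#' tumor-suppressor partner — and couples each to the count matrix.
#' Decoys cycle through adjacent-gene read-throughs, ribosomal partners,
#' mitochondrial partners and low-support candidates.  Junction tables
#' carry the configured exon-skipping events (true PSI in the carrier,
#' baseline elsewhere, ~0 in thymus) plus null background events.
#'
#' @param config A [sim_config()].
#' @param gene_models From [simulate_gene_models()].
#' @param count_matrix From [simulate_counts()]; its counts are modified to
#'   couple expression consequences and returned.
#' @param seed Integer seed.
#' @return List with `fusions` (data.frame), `junctions` (data.frame with
#'   columns `event_id`, `gene_id`, `sample_id`, `A`, `B`, `C`),
#'   `count_matrix` (expression-coupled), and `truth`.
#' @export
simulate_fusions_and_junctions <- function(config, gene_models, count_matrix,
                                           seed = config$seed) {
  validate_sim_config(config)
  counts <- count_matrix$counts
  meta <- count_matrix$sample_meta
  tumors <- meta$sample_id[meta$sample_type != "thymus"]
  patients <- meta$sample_id[meta$sample_type == "patient"]
  with_seed(seed, {
    gm <- gene_models
    clean <- gm$gene_id[!gm$is_ribosomal & !gm$is_chrM]
    classes <- rep_len(c("chimeric_protein", "partner_overexpression",
                         "partner_inactivation"),
                       config$n_true_fusions)
    rows <- list(); truth_rows <- list()
    fid <- 0L
    mk <- function(sample, g5, g3, span, split, frame) {
      fid <<- fid + 1L
      i5 <- match(g5, gm$gene_id); i3 <- match(g3, gm$gene_id)
      data.frame(fusion_id = sprintf("F%03d", fid), sample_id = sample,
                 gene5p = g5, gene3p = g3,
                 chrom5p = gm$chrom[i5], pos5p = gm$end[i5],
                 chrom3p = gm$chrom[i3], pos3p = gm$start[i3],
                 spanning_reads = span, split_reads = split,
                 frame_status = frame, stringsAsFactors = FALSE)
    }
    for (cl in classes) {
      carrier <- sample(tumors, 1)
      span <- 8L + rpois(1, 15); split <- 5L + rpois(1, 8)
      if (cl == "chimeric_protein") {
        pair <- sample(clean, 2)
        # force different chromosomes so the pair is never adjacent
        while (gm$chrom[match(pair[1], gm$gene_id)] ==
               gm$chrom[match(pair[2], gm$gene_id)])
          pair <- sample(clean, 2)
        rows[[length(rows) + 1L]] <-
          mk(carrier, pair[1], pair[2], span, split, "in_frame")
        affected <- NA_character_
      } else if (cl == "partner_overexpression") {
        g3 <- sample(clean, 1)
        nb <- downstream_neighbor(gm, g3)
        affected <- if (!is.na(nb) && runif(1) < 0.5 &&
                        !nb %in% c(gm$gene_id[gm$is_ribosomal | gm$is_chrM]))
          nb else g3
        g5 <- sample(setdiff(clean, c(g3, affected)), 1)
        while (gm$chrom[match(g5, gm$gene_id)] ==
               gm$chrom[match(g3, gm$gene_id)])
          g5 <- sample(setdiff(clean, c(g3, affected)), 1)
        rows[[length(rows) + 1L]] <-
          mk(carrier, g5, g3, span, split, "out_of_frame")
        # couple: affected gene strongly over-expressed in the carrier only
        lvl <- max(median(counts[affected, tumors]) + 5, 20)
        counts[affected, carrier] <- as.integer(round(lvl * 64))
      } else {
        tsgs <- intersect(gm$gene_id[gm$is_tsg], clean)
        g5 <- if (length(tsgs)) sample(tsgs, 1) else sample(clean, 1)
        g3 <- sample(setdiff(clean, g5), 1)
        while (gm$chrom[match(g5, gm$gene_id)] ==
               gm$chrom[match(g3, gm$gene_id)])
          g3 <- sample(setdiff(clean, g5), 1)
        rows[[length(rows) + 1L]] <-
          mk(carrier, g5, g3, span, split, "out_of_frame")
        affected <- g5
        counts[g5, carrier] <- as.integer(round(counts[g5, carrier] / 16))
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        fusion_id = sprintf("F%03d", fid), class = cl,
        affected_gene = affected, stringsAsFactors = FALSE)
    }
    # decoys
    kinds <- rep_len(c("adjacent", "ribosomal", "chrM", "low_support"),
                     config$n_decoy_fusions)
    for (kind in kinds) {
      carrier <- sample(tumors, 1)
      span <- 8L + rpois(1, 10); split <- 5L + rpois(1, 5)
      if (kind == "adjacent") {
        repeat {
          g5 <- sample(clean, 1)
          nb <- downstream_neighbor(gm, g5)
          if (!is.na(nb)) break
        }
        rows[[length(rows) + 1L]] <- mk(carrier, g5, nb, span, split,
                                        "out_of_frame")
      } else if (kind == "ribosomal" && any(gm$is_ribosomal)) {
        g5 <- sample(gm$gene_id[gm$is_ribosomal], 1)
        rows[[length(rows) + 1L]] <-
          mk(carrier, g5, sample(clean, 1), span, split, "out_of_frame")
      } else if (kind == "chrM" && any(gm$is_chrM)) {
        g3 <- sample(gm$gene_id[gm$is_chrM], 1)
        rows[[length(rows) + 1L]] <-
          mk(carrier, sample(clean, 1), g3, span, split, "out_of_frame")
      } else {
        pair <- sample(clean, 2)
        low_span <- runif(1) < 0.5
        rows[[length(rows) + 1L]] <- mk(
          carrier, pair[1], pair[2],
          if (low_span) sample(0:7, 1) else span,
          if (low_span) split else sample(0:4, 1), "unknown")
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        fusion_id = sprintf("F%03d", fid), class = paste0("decoy_", kind),
        affected_gene = NA_character_, stringsAsFactors = FALSE)
    }
    fusions <- do.call(rbind, rows)
    fusion_truth <- do.call(rbind, truth_rows)

    # junction tables: planted events + null background events
    ev <- config$skipping_events
    jrows <- list(); jtruth <- list()
    add_event <- function(event_id, gene, carrier_samples, psi, depth,
                          planted) {
      for (s in meta$sample_id) {
        # all non-carriers (thymus included) share a near-zero baseline, so
        # every non-planted tumor-vs-thymus contrast is a true null
        p <- if (s %in% carrier_samples) psi else 0.02
        tot <- rpois(1, depth)
        C <- rbinom(1, tot, p)
        A <- rbinom(1, tot - C, 0.5)
        jrows[[length(jrows) + 1L]] <<- data.frame(
          event_id = event_id, gene_id = gene, sample_id = s,
          A = A, B = tot - C - A, C = C, stringsAsFactors = FALSE)
      }
      jtruth[[length(jtruth) + 1L]] <<- data.frame(
        event_id = event_id, gene_id = gene,
        carrier = paste(carrier_samples, collapse = ","),
        true_psi = psi, planted = planted, stringsAsFactors = FALSE)
    }
    if (!is.null(ev) && nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        gene <- ev$gene[i]
        if (!gene %in% gm$gene_id) gene <- sample(clean, 1)
        carrier <- patients[min(ev$sample_index[i], length(patients))]
        add_event(sprintf("SE%02d", i), gene, carrier, ev$psi[i],
                  ev$depth[i], TRUE)
      }
    }
    n_ev <- if (is.null(ev)) 0L else nrow(ev)
    for (i in seq_len(3L)) {  # null background events
      add_event(sprintf("SE%02d", n_ev + i), sample(clean, 1), character(0),
                0.02, 300, FALSE)
    }
    junctions <- do.call(rbind, jrows)
    count_matrix$counts <- counts
    count_matrix$truth$fusion_truth <- fusion_truth
    count_matrix$truth$junction_truth <- do.call(rbind, jtruth)
    list(fusions = fusions, junctions = junctions,
         count_matrix = count_matrix,
         truth = list(fusions = fusion_truth,
                      junctions = do.call(rbind, jtruth)))
  })
}

#' Simulate exome and RNA variant tables
#'
#' Each tumor sample receives germline het SNPs (carrying population
#' database memberships), planted driver mutations (protein-altering,
#' recurrent in at least two patients per driver gene, a configured
#' fraction carrying COSMIC plus dbSNP membership), somatic passengers
#' (cell lines at triple the patient rate), and small INDELs with explicit
#' homopolymer context.  Every exome variant is re-emitted in RNA as
#' heterozygous, homozygous-variant (allelic imbalance) or absent with
#' configured probabilities, conditional on RNA coverage; RNA depth at a
#' site is proportional to the gene's simulated expression, so unexpressed
#' genes are not callable.  Read-end, repeat-region and thymus-shared
#' artifact calls are added to the RNA table only.
#'
#' @param config A [sim_config()].
#' @param gene_models From [simulate_gene_models()].
#' @param seed Integer seed.
#' @param counts Optional expression-coupled `count_matrix` controlling RNA
#'   depth; when `NULL`, depth is uniform at `mean_depth`.
#' @param sample_meta Optional sample sheet.
#' @return List with `exome_variants`, `rna_variants`, `coverage`
#'   (per-site depth in both assays) and `truth` (planted drivers, germline
#'   ids, the RNA re-emission class of every exome-het site).
#' @export
simulate_variant_tables <- function(config, gene_models, seed = config$seed,
                                    counts = NULL, sample_meta = NULL) {
  validate_sim_config(config)
  if (is.null(sample_meta)) sample_meta <- simulate_sample_meta(config)
  gm <- gene_models
  nuclear <- gm[!gm$is_chrM, , drop = FALSE]
  cm <- if (!is.null(counts)) counts$counts else NULL
  mean_ct <- if (!is.null(cm)) mean(cm) else NA_real_
  with_seed(seed, {
    tumors <- sample_meta[sample_meta$sample_type != "thymus", , drop = FALSE]
    planted <- head(intersect(gm$gene_id, tall_driver_genes),
                    config$n_driver_genes)
    rows <- list()
    vid <- 0L
    new_var <- function(sample, gene_row, origin, terms, is_indel = FALSE,
                        context = NA_character_, anchor = NA_integer_,
                        caller_pass = TRUE, read_end = FALSE,
                        in_dbsnp = FALSE, in_1000g = FALSE, in_cg = FALSE,
                        in_normal_panel = FALSE, in_thymus = FALSE,
                        in_cosmic = FALSE, in_repeat = FALSE) {
      vid <<- vid + 1L
      pos <- gene_row$start + sample.int(gene_row$end - gene_row$start + 1L, 1) - 1L
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- if (is_indel) paste0(ref, strrep("A", sample(1:3, 1)))
             else sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      depth <- max(1L, rpois(1, config$mean_depth))
      vaf <- rbeta(1, 30, 30)
      alt_depth <- pmin(depth, pmax(0L, as.integer(round(vaf * depth))))
      data.frame(
        variant_id = sprintf("V%06d", vid), sample_id = sample,
        chrom = gene_row$chrom, pos = pos, ref = ref, alt = alt,
        depth = depth, alt_depth = alt_depth, vaf = alt_depth / depth,
        read_end_only = read_end, consequence_terms = paste(terms, collapse = ";"),
        gene_id = gene_row$gene_id,
        in_dbsnp = in_dbsnp, in_1000g = in_1000g, in_cg = in_cg,
        in_normal_panel = in_normal_panel, in_thymus = in_thymus,
        in_cosmic = in_cosmic, in_repeat = in_repeat,
        is_indel = is_indel, homopolymer_context = context,
        anchor_pos = anchor, caller_pass = caller_pass,
        origin = origin, stringsAsFactors = FALSE)
    }
    ## planted drivers: >=2 distinct patients per gene
    patients <- sample_meta$sample_id[sample_meta$sample_type == "patient"]
    driver_truth <- list()
    for (g in planted) {
      k <- min(length(patients),
               2L + rpois(1, max(0, config$driver_recurrence - 2)))
      who <- sample(patients, k)
      grow <- gm[gm$gene_id == g, ]
      for (s in who) {
        dbhit <- runif(1) < config$cosmic_overlap_rate
        term <- sample(c("missense-variant", "stop-gained",
                         "splice-donor-variant"), 1,
                       prob = c(0.8, 0.15, 0.05))
        rows[[length(rows) + 1L]] <-
          new_var(s, grow, "driver", term,
                  in_dbsnp = dbhit, in_cosmic = dbhit)
      }
      driver_truth[[g]] <- who
    }
    ## germline, passengers, indels, artifacts per tumor sample
    benign <- c("synonymous-variant", "intron-variant", "3-prime-UTR-variant")
    for (si in seq_len(nrow(tumors))) {
      s <- tumors$sample_id[si]
      n_germ <- rpois(1, config$germline_rate)
      if (n_germ > 0) {
        gidx <- sample.int(nrow(nuclear), n_germ, replace = TRUE)
        for (i in gidx) {
          rows[[length(rows) + 1L]] <- new_var(
            s, nuclear[i, ], "germline",
            sample(c(benign, "missense-variant"), 1, prob = c(.3, .3, .2, .2)),
            in_dbsnp = runif(1) < 0.98, in_1000g = runif(1) < 0.5,
            in_cg = runif(1) < 0.3, in_normal_panel = runif(1) < 0.4)
        }
      }
      rate <- config$passenger_rate *
        if (tumors$sample_type[si] == "cell_line") 3 else 1
      n_pass <- rpois(1, rate)
      for (i in seq_len(n_pass)) {
        rows[[length(rows) + 1L]] <- new_var(
          s, nuclear[sample.int(nrow(nuclear), 1), ], "passenger",
          sample(c("missense-variant", "synonymous-variant"), 1,
                 prob = c(0.6, 0.4)))
      }
      n_indel <- rpois(1, 4)
      for (i in seq_len(n_indel)) {
        bad <- runif(1) < 0.4
        run <- if (bad) sample(6:9, 1) else sample(2:5, 1)
        ctx <- paste0("TC", strrep("A", run), "GT")
        rows[[length(rows) + 1L]] <- new_var(
          s, nuclear[sample.int(nrow(nuclear), 1), ],
          if (bad) "homopolymer_artifact" else "somatic_indel",
          sample(c("frameshift-variant", "inframe-deletion"), 1),
          is_indel = TRUE, context = ctx, anchor = 3L,
          caller_pass = runif(1) < 0.95)
      }
    }
    exome <- do.call(rbind, rows)

    ## RNA re-emission conditional on expression-scaled coverage
    expr_factor <- function(gene, sample) {
      if (is.null(cm) || !(gene %in% rownames(cm)) ||
          !(sample %in% colnames(cm))) return(1)
      cm[gene, sample] / mean_ct
    }
    n_ex <- nrow(exome)
    rna_depth <- integer(n_ex)
    for (i in seq_len(n_ex))
      rna_depth[i] <- rpois(1, config$mean_depth *
                              expr_factor(exome$gene_id[i], exome$sample_id[i]))
    # driver genes are expressed in T-ALL (floored in the count model);
    # keep their variant sites comfortably callable
    rna_depth[exome$origin == "driver"] <-
      pmax(rna_depth[exome$origin == "driver"], 25L)
    p_hom <- config$allelic_imbalance_fraction
    p_het <- config$rna_het_rate
    u <- runif(n_ex)
    class <- ifelse(u < p_hom, "hom_var",
                    ifelse(u < p_hom + p_het, "het", "absent"))
    class[exome$origin == "driver"] <- "het"   # drivers are expressed and called
    class[rna_depth < 8] <- "absent"           # not expressed -> not callable
    rna <- exome[class != "absent", , drop = FALSE]
    kl <- class[class != "absent"]
    rd <- rna_depth[class != "absent"]
    if (nrow(rna) > 0) {
      vaf <- ifelse(kl == "hom_var", runif(nrow(rna), 0.9, 1),
                    rbeta(nrow(rna), 30, 30))
      rna$depth <- pmax(1L, rd)
      rna$alt_depth <- pmin(rna$depth, pmax(0L, as.integer(round(vaf * rna$depth))))
      rna$vaf <- rna$alt_depth / rna$depth
    }
    ## RNA-only artifacts
    arows <- list()
    for (si in seq_len(nrow(tumors))) {
      s <- tumors$sample_id[si]
      n_art <- rpois(1, config$artifact_rate)
      for (i in seq_len(n_art)) {
        kind <- sample(c("read_end", "repeat", "thymus"), 1)
        arows[[length(arows) + 1L]] <- new_var(
          s, nuclear[sample.int(nrow(nuclear), 1), ], paste0("artifact_", kind),
          "missense-variant",
          read_end = kind == "read_end", in_repeat = kind == "repeat",
          in_thymus = kind == "thymus")
      }
    }
    if (length(arows)) rna <- rbind(rna, do.call(rbind, arows))
    rownames(exome) <- rownames(rna) <- NULL

    coverage <- data.frame(
      sample_id = exome$sample_id, chrom = exome$chrom, pos = exome$pos,
      exome_depth = exome$depth, rna_depth = rna_depth,
      stringsAsFactors = FALSE)
    list(exome_variants = exome, rna_variants = rna, coverage = coverage,
         truth = list(planted_drivers = driver_truth,
                      germline_ids = exome$variant_id[exome$origin == "germline"],
                      rna_class = setNames(class, exome$variant_id)))
  })
}

#' Simulate a complete cohort bundle
#'
#' Runs all component generators in order (gene models, counts, fusions and
#' junctions with expression coupling, variant tables with
#' expression-scaled RNA depth) under per-stage child seeds derived from
#' one master seed, and assembles the truth record.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (default `config$seed`).
#' @return A `cohort_bundle`: list with `gene_models`, `sample_meta`,
#'   `count_matrix`, `fusions`, `junctions`, `exome_variants`,
#'   `rna_variants`, `coverage`, `truth`, `config`, `seed`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  gm <- simulate_gene_models(config, stage_seed(seed, "genes"))
  meta <- simulate_sample_meta(config)
  cm <- simulate_counts(config, gm, stage_seed(seed, "counts"), meta)
  fj <- simulate_fusions_and_junctions(config, gm, cm,
                                       stage_seed(seed, "fusions"))
  vt <- simulate_variant_tables(config, gm, stage_seed(seed, "variants"),
                                counts = fj$count_matrix, sample_meta = meta)
  structure(list(
    gene_models = gm, sample_meta = meta, count_matrix = fj$count_matrix,
    fusions = fj$fusions, junctions = fj$junctions,
    exome_variants = vt$exome_variants, rna_variants = vt$rna_variants,
    coverage = vt$coverage,
    truth = c(fj$truth, vt$truth,
              fj$count_matrix$truth[c("batch_shifts", "subtype_signatures")]),
    config = config, seed = seed), class = "cohort_bundle")
}
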