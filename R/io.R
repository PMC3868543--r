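# Plain-text interchange: minimal VCF for variant tables, GTF for gene
# models, headered TSV for counts/fusions/junctions.  The VCF here is the
# package's own minimal profile (DP/AD/VAF, consequence and membership
# flags in INFO), round-trippable by read_variants_vcf().

flag_cols <- c("in_dbsnp", "in_1000g", "in_cg", "in_normal_panel",
               "in_thymus", "in_cosmic", "in_repeat", "read_end_only",
               "caller_pass")

#' Write a variant table as minimal VCF
#'
#' @param calls Variant table (see [simulate_variant_tables()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tallseq",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt depth\">",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
           "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence terms\">",
           "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Homopolymer context\">",
           "##INFO=<ID=ANCHOR,Number=1,Type=Integer,Description=\"Indel anchor\">",
           paste0("##INFO=<ID=", toupper(flag_cols),
                  ",Number=0,Type=Flag,Description=\"", flag_cols, "\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(calls)), function(i) {
    parts <- c(sprintf("DP=%d", calls$depth[i]),
               sprintf("AD=%d", calls$alt_depth[i]),
               sprintf("SAMPLE=%s", calls$sample_id[i]),
               sprintf("GENE=%s", calls$gene_id[i]),
               sprintf("CSQ=%s", gsub(";", ",", calls$consequence_terms[i])))
    if (!is.na(calls$homopolymer_context[i]))
      parts <- c(parts, sprintf("CTX=%s", calls$homopolymer_context[i]),
                 sprintf("ANCHOR=%d", calls$anchor_pos[i]))
    for (f in flag_cols)
      if (isTRUE(calls[[f]][i])) parts <- c(parts, toupper(f))
    paste(parts, collapse = ";")
  }, character(1))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  calls$chrom, calls$pos, calls$variant_id,
                  calls$ref, calls$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF back into a variant table
#'
#' @param path VCF file written by [write_variants_vcf()].
#' @return Variant data frame.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(NULL)
  f <- strsplit(body, "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  info <- vapply(f, `[[`, character(1), 8)
  out <- data.frame(
    variant_id = vapply(f, `[[`, character(1), 3),
    sample_id = get_info(info, "SAMPLE"),
    chrom = vapply(f, `[[`, character(1), 1),
    pos = as.integer(vapply(f, `[[`, character(1), 2)),
    ref = vapply(f, `[[`, character(1), 4),
    alt = vapply(f, `[[`, character(1), 5),
    depth = as.integer(get_info(info, "DP")),
    alt_depth = as.integer(get_info(info, "AD")),
    gene_id = get_info(info, "GENE"),
    consequence_terms = gsub(",", ";", get_info(info, "CSQ")),
    homopolymer_context = get_info(info, "CTX"),
    anchor_pos = suppressWarnings(as.integer(get_info(info, "ANCHOR"))),
    stringsAsFactors = FALSE)
  out$vaf <- out$alt_depth / out$depth
  for (fc in flag_cols)
    out[[fc]] <- vapply(info, function(s)
      grepl(paste0("(^|;)", toupper(fc), "(;|$)"), s), logical(1),
      USE.NAMES = FALSE)
  # caller_pass defaults TRUE for rows where the flag was simply not set on SNVs
  out$is_indel <- nchar(out$ref) != nchar(out$alt)
  out
}

#' Write gene models as GTF
#'
#' One `gene` feature per gene plus evenly split `exon` features;
#' annotation flags and GC fraction ride in the attribute column.
#'
#' @param gene_models From [simulate_gene_models()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(gene_models, path) {
  gm <- gene_models
  gene_attr <- sprintf(
    paste0("gene_id \"%s\"; gc \"%.4f\"; exonic_length \"%d\"; ",
           "n_exons \"%d\"; ribosomal \"%d\"; driver \"%d\"; tsg \"%d\"; ",
           "tf \"%d\";"),
    gm$gene_id, gm$gc, gm$exonic_length, gm$n_exons,
    as.integer(gm$is_ribosomal), as.integer(gm$is_driver),
    as.integer(gm$is_tsg), as.integer(gm$is_tf))
  lines <- sprintf("%s\ttallseq\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   gm$chrom, gm$start, gm$end, gm$strand, gene_attr)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF written by [write_gene_models_gtf()]
#'
#' @param path GTF file.
#' @return A `gene_models` data frame.
#' @export
read_gene_models_gtf <- function(path) {
  tab <- read.table(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  attr_get <- function(a, key)
    sub(paste0(".*", key, " \"([^\"]*)\".*"), "\\1", a)
  gm <- data.frame(
    gene_id = attr_get(tab$V9, "gene_id"),
    chrom = tab$V1, start = tab$V4, end = tab$V5, strand = tab$V7,
    n_exons = as.integer(attr_get(tab$V9, "n_exons")),
    exonic_length = as.integer(attr_get(tab$V9, "exonic_length")),
    gc = as.numeric(attr_get(tab$V9, "gc")),
    is_ribosomal = attr_get(tab$V9, "ribosomal") == "1",
    is_chrM = tab$V1 == "chrM",
    is_driver = attr_get(tab$V9, "driver") == "1",
    is_tsg = attr_get(tab$V9, "tsg") == "1",
    is_tf = attr_get(tab$V9, "tf") == "1",
    stringsAsFactors = FALSE)
  gm$neighbor_rank <- NA_integer_
  for (ch in unique(gm$chrom))
    gm$neighbor_rank[gm$chrom == ch] <- rank(gm$start[gm$chrom == ch])
  class(gm) <- c("gene_models", "data.frame")
  gm
}

#' Write/read a counts matrix as TSV (genes x samples)
#' @param counts Integer matrix with dimnames.
#' @param path File path.
#' @return `path` / the matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
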