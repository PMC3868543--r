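#' Curated T-ALL driver genes
#'
#' The 47 genes recurrently altered in T-cell acute lymphoblastic leukemia,
#' curated from the Cancer Gene Census and the T-ALL literature.  The
#' cohort simulator seeds its planted driver set from this list, and the
#' exon-skipping scan can be restricted to it.
#'
#' @format Character vector of 47 HGNC symbols.
#' @export
tall_driver_genes <- c(
  "TLX1", "TLX3", "PHF6", "MYC", "BCL11B", "HOXA1", "SET", "MLL", "MLLT1",
  "PICALM", "MLLT10", "WT1", "MYB", "LEF1", "LMO2", "LMO1", "TAL1", "NUP98",
  "NOTCH1", "FBXW7", "CCND2", "PTEN", "PTPN2", "NF1", "FLT3", "JAK1", "NRAS",
  "LCK", "NUP214", "ABL1", "EZH2", "SETD2", "SUZ12", "JAK3", "MEF2C",
  "NKX2-1", "NKX2-2", "CDKN2A", "CDKN2B", "RUNX1", "KRAS", "EED", "ETV6",
  "RPL10", "DNM2", "IL7R", "CNOT3"
)

#' Subtype-defining transcription factors
#'
#' Transcription factors whose ectopic over-expression defines the major
#' T-ALL molecular subtypes; their expression patterns alone discriminate
#' the cohort into six clusters.
#'
#' @format Character vector of 6 HGNC symbols.
#' @export
tall_subtype_tfs <- c("TAL1", "TLX1", "TLX3", "NKX2-5", "LYL1", "LMO2")

# Tumor-suppressor subset used for fusion-inactivation calls; drawn from
# the driver list plus TP53/IKZF1 which enter the simulated universe too.
tall_tumor_suppressors <- c(
  "PHF6", "WT1", "FBXW7", "PTEN", "NF1", "SETD2", "SUZ12", "CDKN2A",
  "CDKN2B", "RUNX1", "EED", "ETV6", "TP53", "IKZF1"
)

#' Protein-altering consequence terms
#'
#' Variant-annotation consequence terms treated as protein-altering.  SNVs
#' use the base set; INDELs additionally admit in-frame and frameshift
#' terms.
#'
#' @param class `"snv"` or `"indel"`.
#' @return Character vector of consequence terms.
#' @export
protein_altering_terms <- function(class = c("snv", "indel")) {
  class <- match.arg(class)
  snv <- c(
    "splice-donor-variant", "splice-acceptor-variant", "stop-gained",
    "initiator-codon-variant", "missense-variant", "splice-region-variant"
  )
  if (class == "snv") snv else
    c(snv, "inframe-insertion", "inframe-deletion", "frameshift-variant")
}

# Terms the annotator may emit that are recognized but not protein-altering.
known_benign_terms <- c(
  "synonymous-variant", "stop-retained-variant", "intron-variant",
  "5-prime-UTR-variant", "3-prime-UTR-variant", "upstream-gene-variant",
  "downstream-gene-variant", "non-coding-transcript-variant",
  "intergenic-variant"
)
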