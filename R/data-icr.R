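# Built-in worked-example data for the ICR hereditary-cataract rat model:
# the reported candidate variants, the SSLP markers delimiting the Cati1 and
# Cati2 loci, and the one known panel-membership fact. These are the
# desk-scale inputs on which the funnel's published endpoint (4 candidate
# genes in Cati2, Apoc3 and RGD1305464 in the Thy1-Cyp1a1 window of Cati1)
# can be reproduced without any download.

icr_file <- function(name) {
  system.file("extdata", name, package = "catifunnel", mustWork = TRUE)
}

#' Reported ICR candidate variants
#'
#' The homozygous coding variants reported for the ICR cortical-cataract rat
#' (mRatBN7.2 coordinates): the chromosome-8 Cati1-window candidates
#' (*Apoc3*, *RGD1305464*), the five chromosome-15 variants relevant to the
#' Cati2 locus (*Phf11b*, *Fdft1*, *Ppk*, *Nkx2-6*, *Sucla2*) and the two
#' off-locus candidates (*Gja8*, *Srebf2*).
#'
#' @return A variant table ([variant_records()]).
#' @export
icr_reported_variants <- function() {
  df <- utils::read.delim(icr_file("icr_candidate_variants.tsv"), sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  variant_records(df$chrom, df$pos, df$ref, df$alt, genotype = df$genotype,
                  gene = df$gene, so_terms = df$so_terms,
                  assembly = df$assembly)
}

#' SSLP markers of the Cati1 and Cati2 cataract loci
#'
#' Published mRatBN7.2 positions of the markers delimiting *Cati1*
#' (D8Rat68–D8N136, with the finer Thy1–Cyp1a1 window) and the *Cati2*
#' anchor D15Rat20. The two Rnor_6.0 rows are synthetic placeholders whose
#' absolute positions are arbitrary; only their inter-marker distance
#' (20,135,471 bases between D15Rat52 and D15Rat20) is real, so they
#' demonstrate [estimate_marker_position()] faithfully.
#'
#' @return A marker table ([read_marker_table()]).
#' @export
icr_marker_table <- function() {
  read_marker_table(icr_file("icr_markers.tsv"))
}

#' Known panel-shared ICR variant (synthetic panel stand-in)
#'
#' A minimal stand-in for the non-affected strain panel: one strain carrying
#' the *Fdft1* chr15 variant, the published membership fact that removes
#' *Fdft1* from the candidate list at the panel-exclusion stage.
#'
#' @return A named list of variant tables, one per panel strain, suitable
#'   for [panel_exclusion()].
#' @export
icr_panel_stub <- function() {
  df <- utils::read.delim(icr_file("icr_panel_shared.tsv"), sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  out <- lapply(split(df, df$strain), function(s) {
    variant_records(s$chrom, s$pos, s$ref, s$alt, genotype = s$genotype,
                    gene = "", so_terms = "", assembly = "mRatBN7.2")
  })
  out
}
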