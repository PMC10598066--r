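#' Construct a table of variant records
#'
#' The package represents a call set as a plain `data.frame` with one row
#' per (chrom, pos, ref, alt) atom — multi-allelic sites are decomposed
#' before any filtering stage runs. Several sequence-ontology consequence
#' terms may annotate one allele; they are stored `&`-joined in a single
#' string, the convention used by SnpEff-style ANN annotation.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions (first aligned base, VCF convention).
#' @param ref,alt Reference and alternate allele strings (non-empty,
#'   `ref != alt`).
#' @param genotype One of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @param gene Gene symbol (may be `""` for intergenic records).
#' @param so_terms Sequence-ontology consequence terms, `&`-joined when a
#'   record carries several (e.g. `"splice_donor_variant&intron_variant"`).
#' @param assembly Reference assembly label (e.g. `"mRatBN7.2"`).
#' @param impact Optional impact class; when `NULL` (default) it is derived
#'   from `so_terms` via [classify_impact()], which is the invariant the
#'   package maintains everywhere.
#'
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`, `gene`, `so_terms`, `impact`, `assembly`.
#' @export
variant_records <- function(chrom, pos, ref, alt,
                            genotype = "hom_alt", gene = "",
                            so_terms = "", assembly = "",
                            impact = NULL) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.numeric(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    genotype = rep_len(as.character(genotype), n),
    gene = rep_len(as.character(gene), n),
    so_terms = rep_len(as.character(so_terms), n),
    assembly = rep_len(as.character(assembly), n),
    stringsAsFactors = FALSE
  )
  if (n > 0L) {
    if (any(df$pos < 1)) stop("pos must be >= 1 (1-based coordinates)")
    if (any(!nzchar(df$ref)) || any(!nzchar(df$alt))) {
      stop("ref and alt alleles must be non-empty")
    }
    if (any(df$ref == df$alt)) stop("ref and alt must differ")
    bad <- setdiff(unique(df$genotype), c("hom_ref", "het", "hom_alt", "missing"))
    if (length(bad) > 0L) stop("invalid genotype value(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(impact)) {
    df$impact <- vapply(df$so_terms, function(s)
      classify_impact(split_so_terms(s)), "", USE.NAMES = FALSE)
  } else {
    df$impact <- rep_len(as.character(impact), n)
  }
  df[, c("chrom", "pos", "ref", "alt", "genotype", "gene",
         "so_terms", "impact", "assembly")]
}

empty_variants <- function(assembly = "") {
  variant_records(character(), numeric(), character(), character(),
                  assembly = assembly)
}

split_so_terms <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  strsplit(s, "&", fixed = TRUE)[[1L]]
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")

# canonical row order used by all serialized outputs
sort_variants <- function(v) {
  if (nrow(v) == 0L) return(v)
  v <- v[order(v$chrom, v$pos, v$ref, v$alt, method = "radix"), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Sequence-ontology impact classification table
#'
#' The conventional mapping from sequence-ontology consequence terms to the
#' four-level annotation-impact vocabulary (`HIGH` > `MODERATE` > `LOW` >
#' `MODIFIER`), as popularized by SnpEff/VEP ANN annotation. `MODERATE`
#' covers missense changes and in-frame insertions/deletions of whole
#' codons; `HIGH` covers consequences expected to severely alter the gene
#' product (frameshifts, gained/lost stop codons, splice-site disruption).
#'
#' @return A named character vector mapping SO term to impact class.
#' @export
so_impact_table <- function() {
  c(
    # HIGH: severe disruption of the gene product
    chromosome_number_variation = "HIGH",
    exon_loss_variant = "HIGH",
    frameshift_variant = "HIGH",
    rare_amino_acid_variant = "HIGH",
    splice_acceptor_variant = "HIGH",
    splice_donor_variant = "HIGH",
    start_lost = "HIGH",
    stop_gained = "HIGH",
    stop_lost = "HIGH",
    transcript_ablation = "HIGH",
    # MODERATE: amino-acid-level changes preserving the reading frame
    coding_sequence_variant = "MODERATE",
    conservative_inframe_deletion = "MODERATE",
    conservative_inframe_insertion = "MODERATE",
    disruptive_inframe_deletion = "MODERATE",
    disruptive_inframe_insertion = "MODERATE",
    inframe_deletion = "MODERATE",
    inframe_insertion = "MODERATE",
    missense_variant = "MODERATE",
    protein_altering_variant = "MODERATE",
    regulatory_region_ablation = "MODERATE",
    # LOW: coding but unlikely to change the protein
    incomplete_terminal_codon_variant = "LOW",
    initiator_codon_variant = "LOW",
    splice_region_variant = "LOW",
    start_retained_variant = "LOW",
    stop_retained_variant = "LOW",
    synonymous_variant = "LOW",
    # MODIFIER: non-coding / positional annotations
    `3_prime_UTR_variant` = "MODIFIER",
    `5_prime_UTR_variant` = "MODIFIER",
    downstream_gene_variant = "MODIFIER",
    intergenic_region = "MODIFIER",
    intergenic_variant = "MODIFIER",
    intragenic_variant = "MODIFIER",
    intron_variant = "MODIFIER",
    non_coding_transcript_exon_variant = "MODIFIER",
    non_coding_transcript_variant = "MODIFIER",
    upstream_gene_variant = "MODIFIER"
  )
}

impact_severity_order <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Classify the impact of a variant from its consequence terms
#'
#' Each term is mapped through the impact rule and the most severe class
#' wins (`HIGH` > `MODERATE` > `LOW` > `MODIFIER`). Terms absent from the
#' rule are ignored unless no term is known, in which case the record is
#' classed `UNCLASSIFIED` rather than silently dropped.
#'
#' @param so_terms Character vector of sequence-ontology term names (an
#'   `&`-joined string is also accepted).
#' @param rule Named character vector mapping SO term to impact class;
#'   defaults to [so_impact_table()] and may be overridden (e.g. from a
#'   config file) to change the shipped vocabulary.
#' @return One of `"HIGH"`, `"MODERATE"`, `"LOW"`, `"MODIFIER"`,
#'   `"UNCLASSIFIED"`.
#' @examples
#' classify_impact("missense_variant")                       # MODERATE
#' classify_impact(c("splice_donor_variant", "intron_variant")) # HIGH
#' @export
classify_impact <- function(so_terms, rule = so_impact_table()) {
  if (length(so_terms) == 1L && grepl("&", so_terms, fixed = TRUE)) {
    so_terms <- split_so_terms(so_terms)
  }
  so_terms <- so_terms[!is.na(so_terms) & nzchar(so_terms)]
  if (length(so_terms) == 0L) return("UNCLASSIFIED")
  classes <- rule[so_terms]
  classes <- classes[!is.na(classes)]
  if (length(classes) == 0L) return("UNCLASSIFIED")
  impact_severity_order[min(match(classes, impact_severity_order))]
}

# most severe single SO term of a record; used as part of the
# gene-anchored cross-assembly matching key
top_so_term <- function(so_string, rule = so_impact_table()) {
  terms <- split_so_terms(so_string)
  if (length(terms) == 0L) return("")
  sev <- match(rule[terms], impact_severity_order)
  sev[is.na(sev)] <- length(impact_severity_order) + 1L
  terms[which.min(sev)]
}
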