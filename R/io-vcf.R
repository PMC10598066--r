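# VCF reading goes through vcfR; this file only adapts its matrices to the
# package's per-allele variant table and parses the SnpEff-style ANN field.

parse_gt_for_allele <- function(gt, allele_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (any(alleles == ".")) return("missing")
  hits <- sum(alleles == as.character(allele_index))
  if (hits >= 2L) "hom_alt" else if (hits == 1L) "het" else "hom_ref"
}

# ANN entries: "Allele|Annotation|Annotation_Impact|Gene_Name|..." separated
# by commas; Annotation may be several SO terms joined by '&'.
parse_ann_field <- function(info, alt_allele, site_label) {
  m <- regmatches(info, regexec("(?:^|;)ANN=([^;]*)", info))[[1L]]
  if (length(m) < 2L) {
    warning("no ANN annotation at ", site_label, "; record kept UNCLASSIFIED",
            call. = FALSE)
    return(list(gene = "", so_terms = "", ok = FALSE))
  }
  entries <- strsplit(m[2L], ",", fixed = TRUE)[[1L]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  mine <- fields[vapply(fields, function(f) length(f) >= 1L && f[1L] == alt_allele,
                        NA)]
  if (length(mine) == 0L) {
    warning("no ANN entry for allele ", alt_allele, " at ", site_label,
            "; record kept UNCLASSIFIED", call. = FALSE)
    return(list(gene = "", so_terms = "", ok = FALSE))
  }
  # the gene field may be empty (intergenic records), in which case a
  # trailing '|' is dropped by the split; 3 fields are still parseable
  bad <- vapply(mine, function(f) length(f) < 3L, NA)
  if (any(bad)) {
    warning("unparseable ANN entry at ", site_label,
            "; record kept UNCLASSIFIED", call. = FALSE)
    mine <- mine[!bad]
    if (length(mine) == 0L) return(list(gene = "", so_terms = "", ok = FALSE))
  }
  terms <- unique(unlist(lapply(mine, function(f) split_so_terms(f[2L]))))
  genes <- unique(vapply(mine, function(f)
    if (length(f) >= 4L) f[4L] else "", ""))
  genes <- genes[nzchar(genes) & !is.na(genes)]
  list(gene = if (length(genes) > 0L) genes[1L] else "",
       so_terms = paste(terms, collapse = "&"), ok = TRUE)
}

#' Read an annotated VCF into a variant table
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}) holding a single case sample,
#' decomposes multi-allelic sites into one record per ALT allele, maps the
#' GT field to a zygosity class and parses the SnpEff-style `ANN` INFO field
#' (pipe-delimited `Allele|Annotation|Impact|Gene|...`) into
#' sequence-ontology terms and a gene symbol. The impact class is always
#' recomputed from the SO terms through [classify_impact()] so that it stays
#' a pure function of the annotation; records whose ANN entry cannot be
#' parsed are kept with impact `UNCLASSIFIED` and a warning.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param assembly_label Assembly tag stored on every record (e.g.
#'   `"mRatBN7.2"`).
#' @param chrom_allow Optional character vector restricting records to an
#'   allow-list of chromosomes (e.g. autosomes only); `NULL` keeps all.
#' @param rule Impact rule passed to [classify_impact()].
#' @return A variant table as produced by [variant_records()].
#' @export
read_vcf <- function(path, assembly_label, chrom_allow = NULL,
                     rule = so_impact_table()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (nrow(fix) == 0L) return(empty_variants(assembly_label))
  if (ncol(v@gt) < 2L) stop("VCF has no sample column: ", path)
  fmt <- v@gt[, 1L]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(k) match("GT", k), NA_integer_)
  if (any(is.na(gt_idx))) stop("missing GT in FORMAT field: ", path)
  sample_field <- v@gt[, 2L]
  gt <- mapply(function(s, i) {
    if (is.na(s)) return(NA_character_)
    strsplit(s, ":", fixed = TRUE)[[1L]][i]
  }, sample_field, gt_idx, USE.NAMES = FALSE)

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    site <- sprintf("%s:%s", fix[i, "CHROM"], fix[i, "POS"])
    recs <- lapply(seq_along(alts), function(a) {
      ann <- parse_ann_field(fix[i, "INFO"], alts[a], site)
      data.frame(
        chrom = fix[i, "CHROM"],
        pos = as.numeric(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[a],
        genotype = parse_gt_for_allele(gt[i], a),
        gene = ann$gene,
        so_terms = ann$so_terms,
        assembly = assembly_label,
        stringsAsFactors = FALSE
      )
    })
    rows[[i]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  if (!is.null(chrom_allow)) out <- out[out$chrom %in% chrom_allow, , drop = FALSE]
  res <- variant_records(out$chrom, out$pos, out$ref, out$alt,
                         genotype = out$genotype, gene = out$gene,
                         so_terms = out$so_terms, assembly = assembly_label)
  res$impact <- vapply(res$so_terms, function(s)
    classify_impact(split_so_terms(s), rule), "", USE.NAMES = FALSE)
  res
}

#' Write a variant table as a minimal annotated VCF
#'
#' Emits the VCF 4.2 subset the pipeline consumes: CHROM, POS, ID, REF, ALT,
#' QUAL, FILTER, an `ANN` INFO field (`Allele|Annotation|Impact|Gene`) and a
#' single-sample GT column. One line is written per record; multi-allelic
#' sites are not re-joined. `read_vcf(write_vcf(x))` preserves chrom, pos,
#' alleles, genotype, gene and SO terms.
#'
#' @param variants A variant table ([variant_records()]).
#' @param path Output path (plain text).
#' @param sample_name Name of the genotype column. Default `"CASE"`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_name = "CASE") {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name'\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
  v <- sort_variants(variants)
  body <- if (nrow(v) == 0L) character() else {
    ann <- sprintf("ANN=%s|%s|%s|%s", v$alt, v$so_terms, v$impact, v$gene)
    paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE), ".",
          v$ref, v$alt, ".", "PASS", ann, "GT",
          gt_code[v$genotype], sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
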