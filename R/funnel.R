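# Variant-prioritization funnel: homozygosity -> impact class ->
# dual-assembly concordance -> non-affected strain-panel exclusion ->
# marker-defined locus restriction. Every stage is a monotone filter.

#' Keep homozygous-alternate variants
#'
#' Under a recessive model the causal variant must sit on both chromosomes;
#' only `hom_alt` records survive. Heterozygous, hom-ref and missing
#' genotypes are removed (missing data is not evidence of homozygosity).
#'
#' @param variants A variant table ([variant_records()]).
#' @return The filtered table.
#' @export
filter_homozygous <- function(variants) {
  out <- variants[variants$genotype == "hom_alt", , drop = FALSE]
  cf_log("filter_homozygous", nrow(variants), nrow(out))
  rownames(out) <- NULL
  out
}

#' Keep variants of given impact classes
#'
#' @param variants A variant table.
#' @param classes Character vector of impact classes to retain, e.g.
#'   `c("MODERATE", "HIGH")`.
#' @return The filtered table.
#' @export
select_impact <- function(variants, classes) {
  out <- variants[variants$impact %in% classes, , drop = FALSE]
  cf_log("select_impact", nrow(variants), nrow(out),
         list(classes = paste(classes, collapse = "+")))
  rownames(out) <- NULL
  out
}

#' Dual-assembly concordance
#'
#' Keeps a variant called against assembly A only when the call set against
#' assembly B contains a matching variant; reported coordinates stay on
#' assembly A. Because the two assemblies disagree on coordinates, the
#' default matching key is coordinate-free: (gene symbol, ref allele, alt
#' allele, most severe SO term). `key = "coordinate"` switches to exact
#' (chrom, pos, ref, alt) matching, appropriate when both call sets are on
#' the same assembly.
#'
#' @param set_a Variant table on the reporting assembly.
#' @param set_b Variant table on the other assembly.
#' @param key `"gene"` (default) or `"coordinate"`.
#' @return Rows of `set_a` with a concordant partner in `set_b`. With the
#'   gene key, records missing a gene symbol cannot be matched and are
#'   excluded with a warning.
#' @export
cross_assembly_concordance <- function(set_a, set_b,
                                       key = c("gene", "coordinate")) {
  key <- match.arg(key)
  if (key == "gene") {
    usable_a <- nzchar(set_a$gene)
    usable_b <- nzchar(set_b$gene)
    if (any(!usable_a)) {
      warning(sum(!usable_a),
              " record(s) without a gene symbol excluded from concordance",
              call. = FALSE)
    }
    mk <- function(v) paste(v$gene, v$ref, v$alt,
                            vapply(v$so_terms, top_so_term, "",
                                   USE.NAMES = FALSE), sep = "\r")
    keep <- usable_a & (mk(set_a) %in% mk(set_b)[usable_b])
  } else {
    keep <- variant_key(set_a) %in% variant_key(set_b)
  }
  out <- set_a[keep, , drop = FALSE]
  cf_log("cross_assembly_concordance", nrow(set_a), nrow(out),
         list(key = key))
  rownames(out) <- NULL
  out
}

#' Exclude variants carried by non-affected strains
#'
#' A case variant is removed when any strain of the panel carries a variant
#' with identical (chrom, pos, ref, alt) — any zygosity by default, since a
#' variant present in a cataract-free genome cannot be the ICR-specific
#' cause. `hom_only = TRUE` restricts the exclusion to panel carriers that
#' are themselves homozygous-alternate (the strictly recessive reading).
#'
#' @param case_variants Variant table (same assembly as the panel calls).
#' @param panel Named list of variant tables, one per non-affected strain,
#'   or a single variant table.
#' @param hom_only If `TRUE`, only `hom_alt` panel records exclude.
#' @return The filtered case table.
#' @export
panel_exclusion <- function(case_variants, panel, hom_only = FALSE) {
  if (is.data.frame(panel)) panel <- list(panel)
  seen <- unique(unlist(lapply(panel, function(p) {
    if (hom_only) p <- p[p$genotype == "hom_alt", , drop = FALSE]
    variant_key(p)
  })))
  keep <- !(variant_key(case_variants) %in% seen)
  out <- case_variants[keep, , drop = FALSE]
  cf_log("panel_exclusion", nrow(case_variants), nrow(out),
         list(strains = length(panel), hom_only = hom_only))
  rownames(out) <- NULL
  out
}

#' Restrict variants to a locus interval
#'
#' Keeps variants on the interval's chromosome with
#' `start <= pos <= end`; both endpoints are inclusive, matching the
#' marker-to-marker phrasing of linkage intervals.
#'
#' @param variants Variant table.
#' @param interval A [locus_interval()] (one row).
#' @return The filtered table.
#' @export
restrict_to_locus <- function(variants, interval) {
  stopifnot(nrow(interval) == 1L, interval$start <= interval$end)
  keep <- variants$chrom == interval$chrom &
    variants$pos >= interval$start & variants$pos <= interval$end
  out <- variants[keep, , drop = FALSE]
  cf_log("restrict_to_locus", nrow(variants), nrow(out),
         list(locus = interval$name))
  rownames(out) <- NULL
  out
}

#' Run the variant-prioritization funnel
#'
#' Stage order: homozygosity -> impact selection (the MODERATE and HIGH
#' tracks are counted separately) -> dual-assembly concordance ->
#' strain-panel exclusion -> optional per-locus restriction. Counts are
#' recorded per track at every stage; reported coordinates are those of
#' `case_a`.
#'
#' @param case_a Case call set on the reporting assembly.
#' @param case_b Case call set on the second assembly (for concordance).
#'   `NULL` skips the concordance stage.
#' @param panel Named list of non-affected strain call sets (may be empty).
#' @param loci Optional locus table (rows of [locus_interval()]); when
#'   given, candidates are additionally restricted per locus.
#' @param config A [cati_config()] (recorded in the report).
#' @param concordance_key Passed to [cross_assembly_concordance()].
#' @param panel_hom_only Passed to [panel_exclusion()].
#' @return Object of class `funnel_report`: `stages` (per-track count
#'   table), `candidates` (surviving variants, canonically sorted; union of
#'   loci when `loci` is given), `per_locus` (named list of candidate
#'   tables) and `config`.
#' @export
run_variant_funnel <- function(case_a, case_b = NULL, panel = list(),
                               loci = NULL, config = cati_config(),
                               concordance_key = c("gene", "coordinate"),
                               panel_hom_only = FALSE) {
  concordance_key <- match.arg(concordance_key)
  tracks <- c("MODERATE", "HIGH")
  stages <- list()
  note <- function(stage, track, n_in, n_out, params = "") {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, track = track, n_in = n_in, n_out = n_out,
      params = params, stringsAsFactors = FALSE)
  }

  hom_a <- filter_homozygous(case_a)
  note("homozygous", "all", nrow(case_a), nrow(hom_a))
  hom_b <- if (!is.null(case_b)) filter_homozygous(case_b) else NULL

  survivors <- list()
  for (tr in tracks) {
    sel <- select_impact(hom_a, tr)
    note("impact", tr, nrow(hom_a), nrow(sel), tr)
    if (!is.null(case_b)) {
      sel_b <- select_impact(hom_b, tr)
      conc <- cross_assembly_concordance(sel, sel_b, concordance_key)
      note("concordance", tr, nrow(sel), nrow(conc), concordance_key)
      sel <- conc
    }
    excl <- panel_exclusion(sel, panel, panel_hom_only)
    note("panel_exclusion", tr, nrow(sel), nrow(excl),
         sprintf("%d strains", length(panel)))
    survivors[[tr]] <- excl
  }
  pooled <- sort_variants(do.call(rbind, survivors))

  per_locus <- NULL
  candidates <- pooled
  if (!is.null(loci) && nrow(loci) > 0L) {
    per_locus <- lapply(seq_len(nrow(loci)), function(i) {
      li <- loci[i, , drop = FALSE]
      r <- restrict_to_locus(pooled, li)
      note("locus", "all", nrow(pooled), nrow(r), li$name)
      r
    })
    names(per_locus) <- loci$name
    candidates <- sort_variants(unique(do.call(rbind, per_locus)))
  }

  structure(
    list(stages = do.call(rbind, stages), candidates = candidates,
         per_locus = per_locus, config = config),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Variant-prioritization funnel\n")
  st <- x$stages
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-16s %-9s %8d -> %-8d %s\n", st$stage[i], st$track[i],
                st$n_in[i], st$n_out[i], st$params[i]))
  }
  cat(sprintf("  final candidates: %d variant(s)", nrow(x$candidates)))
  genes <- unique(x$candidates$gene[nzchar(x$candidates$gene)])
  if (length(genes) > 0L) {
    cat(" in gene(s): ", paste(genes, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}
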