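# Report serialization: machine-readable JSON of per-stage counts plus TSVs
# of the surviving items. Counts written to JSON always equal the row counts
# of the corresponding TSVs, and ordering is canonical so reruns are
# byte-identical.

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a serialized variant TSV
#'
#' @param path A TSV written by [write_report()] (columns of
#'   [variant_records()]).
#' @return A variant table.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) return(empty_variants())
  variant_records(df$chrom, as.numeric(df$pos), df$ref, df$alt,
                  genotype = df$genotype, gene = df$gene,
                  so_terms = df$so_terms, assembly = df$assembly)
}

#' Write a report to disk
#'
#' Serializes a report object as JSON (per-stage counts and parameters)
#' plus one TSV per surviving item set. The JSON counts are computed from
#' the same sets that are serialized, so the two views cannot disagree.
#'
#' @param report A `screen_report`, `funnel_report`, `qpcr_validation` or
#'   `study_summary`.
#' @param dir Output directory (created if missing).
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  UseMethod("write_report")
}

#' @export
write_report.screen_report <- function(report, dir) {
  paths <- character()
  sets <- list(case_only_up = report$case_only_up,
               case_only_down = report$case_only_down)
  for (st in names(report$per_strain)) {
    t <- report$per_strain[[st]]$totals
    sets[[paste0(st, "_up_total")]] <- sort(t$up_total)
    sets[[paste0(st, "_down_total")]] <- sort(t$down_total)
  }
  for (nm in names(sets)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv(data.frame(gene = sort(sets[[nm]])), p)
    paths <- c(paths, p)
  }
  json <- list(
    type = "screen_report",
    config = unclass(report$config),
    counts = lapply(sets, length),
    stages = report$counts
  )
  jp <- file.path(dir, "screen_report.json")
  write_json_stable(json, jp)
  invisible(c(paths, jp))
}

#' @export
write_report.funnel_report <- function(report, dir) {
  cand <- sort_variants(report$candidates)
  cp <- file.path(dir, "candidates.tsv")
  write_tsv(cand, cp)
  paths <- cp
  locus_counts <- NULL
  if (!is.null(report$per_locus)) {
    locus_counts <- lapply(report$per_locus, nrow)
    for (nm in names(report$per_locus)) {
      p <- file.path(dir, paste0("candidates_", nm, ".tsv"))
      write_tsv(sort_variants(report$per_locus[[nm]]), p)
      paths <- c(paths, p)
    }
  }
  json <- list(
    type = "funnel_report",
    config = unclass(report$config),
    stages = report$stages,
    n_candidates = nrow(cand),
    per_locus_counts = locus_counts
  )
  jp <- file.path(dir, "funnel_report.json")
  write_json_stable(json, jp)
  invisible(c(paths, jp))
}

#' @export
write_report.qpcr_validation <- function(report, dir) {
  tp <- file.path(dir, "qpcr_tests.tsv")
  cls <- report$classification[order(report$classification$gene), , drop = FALSE]
  cp <- file.path(dir, "qpcr_classification.tsv")
  write_tsv(report$tests, tp)
  write_tsv(cls, cp)
  json <- list(
    type = "qpcr_validation",
    config = unclass(report$config),
    counts = as.list(table(cls$class)),
    n_genes = nrow(cls)
  )
  jp <- file.path(dir, "qpcr_validation.json")
  write_json_stable(json, jp)
  invisible(c(tp, cp, jp))
}
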