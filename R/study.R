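#' Run the full study: expression screen, qPCR validation and variant funnel
#'
#' The three arms are independent lines of evidence; none gates another.
#' Any subset may be supplied — missing arms are skipped and recorded. The
#' summary cross-references the expression case-only increased genes with
#' the genes of the final variant candidates.
#'
#' @param case_matrix,control_matrix Optional [expr_matrix()] pair for the
#'   expression screen.
#' @param ct Optional Ct table for qPCR validation.
#' @param case_a,case_b Optional variant tables for the funnel.
#' @param panel Named list of panel variant tables (funnel arm).
#' @param loci Optional locus table (funnel arm).
#' @param config A [cati_config()].
#' @param ... Further arguments passed to [run_variant_funnel()].
#' @return Object of class `study_summary` with elements `screen`, `qpcr`,
#'   `funnel` (each `NULL` when its arm was skipped), `cross_reference`
#'   (genes in both the expression case-only-up set and the candidate list)
#'   and `skipped`.
#' @export
run_study <- function(case_matrix = NULL, control_matrix = NULL,
                      ct = NULL, case_a = NULL, case_b = NULL,
                      panel = list(), loci = NULL,
                      config = cati_config(), ...) {
  skipped <- character()
  screen <- NULL
  if (!is.null(case_matrix) && !is.null(control_matrix)) {
    screen <- run_expression_screen(case_matrix, control_matrix, config)
  } else {
    skipped <- c(skipped, "expression_screen")
  }
  qpcr <- if (!is.null(ct)) run_qpcr_validation(ct, config) else {
    skipped <- c(skipped, "qpcr_validation")
    NULL
  }
  funnel <- if (!is.null(case_a)) {
    run_variant_funnel(case_a, case_b, panel, loci, config, ...)
  } else {
    skipped <- c(skipped, "variant_funnel")
    NULL
  }

  cross <- character()
  if (!is.null(screen) && !is.null(funnel)) {
    screen_ns <- rownames(case_matrix$signals)
    funnel_ns <- unique(case_a$gene[nzchar(case_a$gene)])
    if (length(intersect(screen_ns, funnel_ns)) == 0L &&
        length(screen_ns) > 0L && length(funnel_ns) > 0L) {
      warning("expression and variant arms share no gene ids; ",
              "cross-reference computed on the (empty) intersection namespace",
              call. = FALSE)
    }
    cand_genes <- unique(funnel$candidates$gene[nzchar(funnel$candidates$gene)])
    cross <- sort(intersect(screen$case_only_up, cand_genes))
  }

  structure(list(screen = screen, qpcr = qpcr, funnel = funnel,
                 cross_reference = cross, skipped = skipped,
                 config = config),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Study summary\n=============\n")
  if (!is.null(x$screen)) print(x$screen) else cat("expression screen: skipped\n")
  if (!is.null(x$qpcr)) print(x$qpcr) else cat("qPCR validation: skipped\n")
  if (!is.null(x$funnel)) print(x$funnel) else cat("variant funnel: skipped\n")
  cat(sprintf("Cross-reference (case-only up genes with candidate variants): %s\n",
              if (length(x$cross_reference) == 0L) "none"
              else paste(x$cross_reference, collapse = ", ")))
  invisible(x)
}

#' @export
write_report.study_summary <- function(report, dir) {
  paths <- character()
  if (!is.null(report$screen)) {
    paths <- c(paths, write_report(report$screen, file.path(dir, "screen")))
  }
  if (!is.null(report$qpcr)) {
    paths <- c(paths, write_report(report$qpcr, file.path(dir, "qpcr")))
  }
  if (!is.null(report$funnel)) {
    paths <- c(paths, write_report(report$funnel, file.path(dir, "funnel")))
  }
  counts <- list(
      case_only_up = if (is.null(report$screen)) NULL
                     else length(report$screen$case_only_up),
      case_only_down = if (is.null(report$screen)) NULL
                       else length(report$screen$case_only_down),
      qpcr_case_only = if (is.null(report$qpcr)) NULL
        else sum(report$qpcr$classification$class == "case_only_increased"),
      funnel_candidates = if (is.null(report$funnel)) NULL
                          else nrow(report$funnel$candidates)
  )
  counts <- counts[!vapply(counts, is.null, NA)]
  json <- list(
    type = "study_summary",
    config = unclass(report$config),
    skipped = as.list(report$skipped),
    cross_reference = as.list(sort(report$cross_reference)),
    counts = counts
  )
  jp <- file.path(dir, "study_summary.json")
  write_json_stable(json, jp)
  invisible(c(paths, jp))
}
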