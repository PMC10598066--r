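# Fold-change screen: low-signal exclusion, group means, asymmetric
# fold-change sets per timepoint contrast, timepoint unions, and
# case-vs-control Venn exclusion.

#' Drop genes below the detection floor
#'
#' A gene is excluded only when *every* sample is strictly below the floor;
#' a single sample at or above it keeps the gene. Applied per strain dataset
#' independently, before group means are computed, on linear-scale signals.
#'
#' @param mat An [expr_matrix()].
#' @param floor Signal floor (> 0); default taken from [cati_config()].
#' @return The filtered `expr_matrix` (sample set unchanged; an empty gene
#'   set is allowed).
#' @export
filter_low_signal <- function(mat, floor = cati_config()$signal_floor) {
  stopifnot(inherits(mat, "expr_matrix"), floor > 0)
  keep <- apply(mat$signals, 1L, function(x) any(x >= floor))
  if (nrow(mat$signals) == 0L) keep <- logical(0)
  out <- expr_matrix(mat$signals[keep, , drop = FALSE], mat$samples)
  cf_log("filter_low_signal", nrow(mat$signals), nrow(out$signals),
         list(floor = floor))
  out
}

#' Per (strain, timepoint) group mean signals
#'
#' Arithmetic mean over replicates, per gene. Single-replicate groups pass
#' through unchanged (the control strain of the screen has n = 1 per
#' timepoint).
#'
#' @param mat An [expr_matrix()].
#' @return A list with `means` (genes x groups matrix, columns named
#'   `"<strain>.<timepoint>"`) and `groups` (`data.frame` of `strain`,
#'   `timepoint`, `n`).
#' @export
group_means <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  s <- mat$samples
  if (nrow(s) == 0L) stop("matrix has no samples, so every group is empty")
  key <- paste(s$strain, s$timepoint, sep = ".")
  groups <- unique(data.frame(strain = s$strain, timepoint = s$timepoint,
                              key = key, stringsAsFactors = FALSE))
  groups <- groups[order(groups$strain, groups$timepoint), , drop = FALSE]
  means <- vapply(groups$key, function(k) {
    cols <- which(key == k)
    rowMeans(mat$signals[, cols, drop = FALSE])
  }, numeric(nrow(mat$signals)))
  if (nrow(mat$signals) == 1L) means <- matrix(means, nrow = 1L,
                                               dimnames = list(rownames(mat$signals), groups$key))
  if (nrow(mat$signals) == 0L) means <- matrix(numeric(), nrow = 0L, ncol = nrow(groups),
                                               dimnames = list(NULL, groups$key))
  groups$n <- vapply(groups$key, function(k) sum(key == k), 0L)
  rownames(groups) <- NULL
  list(means = means, groups = groups[, c("strain", "timepoint", "n")])
}

#' Fold-change gene sets for one timepoint contrast
#'
#' Computes, on group-mean linear signals, the increased set
#' \{g : mean_test/mean_ref > up_threshold\} and the decreased set
#' \{g : mean_ref/mean_test > down_threshold\}; both inequalities are
#' strict ("more than"). Genes with a zero mean in the denominator of a
#' side are excluded from that side and reported in `flagged`.
#'
#' @param gm Output of [group_means()].
#' @param strain `"case"` or `"control"`.
#' @param reference_tp,test_tp Timepoints (weeks) of the contrast.
#' @param config A [cati_config()] supplying the two thresholds.
#' @return An object of class `contrast_sets`: list with `strain`,
#'   `contrast` (`c(reference_tp, test_tp)`), `up`, `down` (gene-id
#'   character vectors) and `flagged` (genes skipped for zero denominators).
#' @export
contrast_sets <- function(gm, strain, reference_tp, test_tp,
                          config = cati_config()) {
  for (tp in c(reference_tp, test_tp)) {
    if (!any(gm$groups$strain == strain & gm$groups$timepoint == tp)) {
      stop(sprintf("no samples for group (%s, %d wk)", strain, tp))
    }
  }
  ref <- gm$means[, paste(strain, reference_tp, sep = ".")]
  tst <- gm$means[, paste(strain, test_tp, sep = ".")]
  genes <- rownames(gm$means)
  up_ok <- ref > 0
  down_ok <- tst > 0
  up <- genes[up_ok & (tst / ref > config$up_threshold)]
  down <- genes[down_ok & (ref / tst > config$down_threshold)]
  flagged <- genes[!up_ok | !down_ok]
  if (length(flagged) > 0L) {
    cf_log("contrast_sets: zero-mean genes skipped", length(genes),
           length(genes) - length(flagged), list(strain = strain))
  }
  structure(
    list(strain = strain, contrast = c(reference_tp, test_tp),
         up = up, down = down, flagged = flagged),
    class = "contrast_sets"
  )
}

#' Union of two contrasts sharing a reference timepoint
#'
#' @param a,b `contrast_sets` objects with the same strain and reference
#'   timepoint.
#' @return A list with `up_total` and `down_total` gene-id vectors
#'   (set unions per direction).
#' @export
union_contrasts <- function(a, b) {
  stopifnot(inherits(a, "contrast_sets"), inherits(b, "contrast_sets"))
  if (a$contrast[1L] != b$contrast[1L]) {
    stop("contrasts do not share a reference timepoint")
  }
  list(up_total = union(a$up, b$up), down_total = union(a$down, b$down))
}

#' Venn exclusion of control-strain genes
#'
#' Set difference `case_set \\ control_set`: genes differentially expressed
#' in the case strain that are *not* also differentially expressed in the
#' control strain (those are attributed to normal maturation).
#'
#' @param case_set,control_set Gene-id character vectors over the same
#'   namespace.
#' @return Character vector of case-only gene ids.
#' @export
strain_exclusion <- function(case_set, control_set) {
  out <- setdiff(case_set, control_set)
  cf_log("strain_exclusion", length(case_set), length(out))
  out
}

#' Run the full two-strain expression screen
#'
#' Pipeline: low-signal filter (per strain) -> group means -> fold-change
#' sets for the 4->8 and 4->10 week contrasts -> per-direction union over
#' the two contrasts -> Venn exclusion of the control-strain sets from the
#' case-strain sets. All stage cardinalities are recorded.
#'
#' @param case_matrix,control_matrix [expr_matrix()] objects sharing a gene
#'   namespace; the case matrix must contain timepoints 4, 8 and 10 weeks.
#' @param config A [cati_config()].
#' @param reference_tp Reference timepoint (weeks, default 4).
#' @param test_tps Test timepoints (default `c(8, 10)`).
#' @return An object of class `screen_report`: per-strain `contrast_sets`,
#'   per-strain unions, `case_only_up` / `case_only_down` gene sets and a
#'   `counts` table of all stage cardinalities.
#' @export
run_expression_screen <- function(case_matrix, control_matrix,
                                  config = cati_config(),
                                  reference_tp = 4, test_tps = c(8, 10)) {
  mats <- list(case = case_matrix, control = control_matrix)
  per_strain <- lapply(names(mats), function(st) {
    # the argument slot, not the metadata, decides which strain a matrix is
    mm <- mats[[st]]
    s <- mm$samples
    s$strain <- st
    m <- filter_low_signal(expr_matrix(mm$signals, s), config$signal_floor)
    gm <- group_means(m)
    cs <- lapply(test_tps, function(tp)
      contrast_sets(gm, st, reference_tp, tp, config))
    names(cs) <- paste0("wk", test_tps)
    totals <- Reduce(function(x, y) list(
      up_total = union(x$up_total, y$up_total),
      down_total = union(x$down_total, y$down_total)
    ), lapply(cs, function(z) list(up_total = z$up, down_total = z$down)))
    list(n_genes_kept = nrow(m$signals), contrasts = cs, totals = totals)
  })
  names(per_strain) <- names(mats)

  case_only_up <- strain_exclusion(per_strain$case$totals$up_total,
                                   per_strain$control$totals$up_total)
  case_only_down <- strain_exclusion(per_strain$case$totals$down_total,
                                     per_strain$control$totals$down_total)

  counts <- do.call(rbind, lapply(names(per_strain), function(st) {
    ps <- per_strain[[st]]
    rbind(
      data.frame(strain = st, stage = "genes_kept", n = ps$n_genes_kept),
      do.call(rbind, lapply(names(ps$contrasts), function(k) {
        cs <- ps$contrasts[[k]]
        data.frame(strain = st,
                   stage = c(paste0("up_", k), paste0("down_", k)),
                   n = c(length(cs$up), length(cs$down)))
      })),
      data.frame(strain = st, stage = c("up_total", "down_total"),
                 n = c(length(ps$totals$up_total), length(ps$totals$down_total)))
    )
  }))
  counts <- rbind(counts,
                  data.frame(strain = "case_only",
                             stage = c("up", "down"),
                             n = c(length(case_only_up), length(case_only_down))))
  rownames(counts) <- NULL

  structure(
    list(per_strain = per_strain,
         case_only_up = sort(case_only_up),
         case_only_down = sort(case_only_down),
         counts = counts,
         config = config),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Two-strain expression screen\n")
  cat(sprintf("  thresholds: up > %g-fold, down > %g-fold; floor %g\n",
              x$config$up_threshold, x$config$down_threshold,
              x$config$signal_floor))
  for (st in names(x$per_strain)) {
    t <- x$per_strain[[st]]$totals
    cat(sprintf("  %-7s: %d up / %d down (union over contrasts)\n",
                st, length(t$up_total), length(t$down_total)))
  }
  cat(sprintf("  case-only: %d up / %d down after Venn exclusion\n",
              length(x$case_only_up), length(x$case_only_down)))
  invisible(x)
}
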