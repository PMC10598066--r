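# RT-qPCR validation: delta-Ct relative quantification against a reference
# gene, a variance-ratio-gated Student/Welch two-sample test, and the
# case-only vs shared-maturation classification.

#' Relative expression from quantification cycles
#'
#' The 2^-dCt model with amplification efficiency 2: one cycle earlier than
#' the reference gene means twice its quantity.
#'
#' @param ct_target Quantification cycle(s) of the target gene.
#' @param ct_reference Quantification cycle(s) of the reference gene
#'   (e.g. Gapdh), same length.
#' @return `2^-(ct_target - ct_reference)`.
#' @examples
#' relative_expression(20, 20)  # 1
#' relative_expression(19, 20)  # 2
#' @export
relative_expression <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^-(ct_target - ct_reference)
}

#' Variance-ratio pre-test for equal variances
#'
#' Two-tailed F-test on `var(x)/var(y)` (via [stats::var.test()]); returns
#' `TRUE` when homoscedasticity is *not* rejected at `alpha`, i.e. when the
#' pooled-variance Student's t-test is admissible. Two all-constant samples
#' have equal variances by construction and return `TRUE`.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param alpha Significance level of the pre-test.
#' @return Logical scalar.
#' @export
homoscedasticity_check <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 2L, length(y) >= 2L, alpha > 0, alpha < 1)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) return(TRUE)
  if (vx == 0 || vy == 0) return(FALSE)  # F-statistic 0 or Inf: reject
  stats::var.test(x, y)$p.value >= alpha
}

#' Homoscedasticity-gated two-sample t-test
#'
#' Runs the two-tailed F-test of [homoscedasticity_check()]; when equal
#' variances are not rejected, a two-tailed Student's t-test with pooled
#' variance is used, otherwise a two-tailed Welch's t-test with
#' Satterthwaite degrees of freedom. Direction is called only at
#' significance: `"up"` if `mean(y) > mean(x)` and `p < alpha_test`,
#' `"down"` if `mean(y) < mean(x)` and `p < alpha_test`, else `"none"`.
#'
#' @param x Reference-group sample (e.g. 4-week relative quantities).
#' @param y Test-group sample (e.g. 8- or 10-week relative quantities).
#' @param config A [cati_config()] providing `alpha_test` and
#'   `alpha_homoscedasticity`.
#' @return A list of class `adaptive_test`: `test_used` (`"student"` or
#'   `"welch"`), `p_value`, `direction`, `mean_x`, `mean_y`, `df`.
#' @export
adaptive_t_test <- function(x, y, config = cati_config()) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  mx <- mean(x); my <- mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # both groups constant: t is 0/0 (equal means) or infinite
    p <- if (mx == my) 1 else 0
    used <- "student"
    df <- length(x) + length(y) - 2L
  } else {
    equal_var <- homoscedasticity_check(x, y, config$alpha_homoscedasticity)
    tt <- stats::t.test(x, y, var.equal = equal_var,
                        alternative = "two.sided")
    p <- tt$p.value
    df <- unname(tt$parameter)
    used <- if (equal_var) "student" else "welch"
  }
  direction <- if (p < config$alpha_test) {
    if (my > mx) "up" else if (my < mx) "down" else "none"
  } else "none"
  structure(list(test_used = used, p_value = p, direction = direction,
                 mean_x = mx, mean_y = my, df = df),
            class = "adaptive_test")
}

#' @export
print.adaptive_test <- function(x, ...) {
  cat(sprintf("%s t-test: p = %.4g (df = %.2f), direction %s\n",
              x$test_used, x$p_value, x$df, x$direction))
  invisible(x)
}

#' Read a Ct table
#'
#' @param path TSV with columns `gene`, `sample_id`, `strain`, `timepoint`,
#'   `ct_target`, `ct_reference`.
#' @return A validated `data.frame`.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_ct_table(df)
}

validate_ct_table <- function(df) {
  required <- c("gene", "sample_id", "strain", "timepoint",
                "ct_target", "ct_reference")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("Ct table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(df$ct_target)) || !all(is.finite(df$ct_reference)) ||
      any(df$ct_target <= 0) || any(df$ct_reference <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  key <- paste(df$gene, df$sample_id, sep = "@")
  if (anyDuplicated(key)) stop("duplicated (gene, sample) row in Ct table")
  df$timepoint <- as.integer(df$timepoint)
  df
}

#' Per-gene adaptive tests on a Ct table
#'
#' Converts each row to a relative quantity via [relative_expression()] and,
#' per gene and strain, tests the reference timepoint against each test
#' timepoint with [adaptive_t_test()].
#'
#' @param ct A Ct table (see [read_ct_table()]).
#' @param config A [cati_config()].
#' @param reference_tp,test_tps Timepoints of the contrasts (weeks).
#' @return `data.frame` with one row per (gene, strain, contrast):
#'   `gene`, `strain`, `reference_tp`, `test_tp`, `test_used`, `p_value`,
#'   `direction`.
#' @export
qpcr_test_table <- function(ct, config = cati_config(),
                            reference_tp = 4, test_tps = c(8, 10)) {
  ct <- validate_ct_table(ct)
  ct$rq <- relative_expression(ct$ct_target, ct$ct_reference)
  out <- list()
  for (g in unique(ct$gene)) {
    for (st in unique(ct$strain[ct$gene == g])) {
      sub <- ct[ct$gene == g & ct$strain == st, , drop = FALSE]
      x <- sub$rq[sub$timepoint == reference_tp]
      for (tp in test_tps) {
        y <- sub$rq[sub$timepoint == tp]
        if (length(x) < 2L || length(y) < 2L) {
          stop(sprintf("gene '%s' (%s): need >= 2 replicates at %d and %d wk",
                       g, st, reference_tp, tp))
        }
        r <- adaptive_t_test(x, y, config)
        out[[length(out) + 1L]] <- data.frame(
          gene = g, strain = st, reference_tp = reference_tp, test_tp = tp,
          test_used = r$test_used, p_value = r$p_value,
          direction = r$direction, stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify validated genes into case-only vs shared increases
#'
#' A gene is `case_only_increased` when it shows a significant increase in
#' the case strain for at least one contrast and no significant increase in
#' the control strain in any contrast; `both_increased` when significantly
#' increased in both strains (shared maturation signal); otherwise
#' `not_validated`. Significant *decrease* in the control strain does not
#' disqualify a case-only call: the rule keys on increases only.
#'
#' @param case_results,control_results Per-strain rows of
#'   [qpcr_test_table()] output (columns `gene`, `direction`, `p_value`).
#' @param alpha Significance level (the `direction` column already encodes
#'   it; `alpha` re-checks consistency).
#' @return `data.frame` with columns `gene` and `class`.
#' @export
classify_validated <- function(case_results, control_results, alpha = 0.05) {
  genes <- unique(case_results$gene)
  missing_ctrl <- setdiff(genes, unique(control_results$gene))
  missing_case <- setdiff(unique(control_results$gene), genes)
  if (length(missing_ctrl) > 0L || length(missing_case) > 0L) {
    stop("genes without results in both strains: ",
         paste(c(missing_ctrl, missing_case), collapse = ", "))
  }
  sig_up <- function(res, g) {
    sub <- res[res$gene == g, , drop = FALSE]
    any(sub$direction == "up" & sub$p_value < alpha)
  }
  cls <- vapply(genes, function(g) {
    case_up <- sig_up(case_results, g)
    ctrl_up <- sig_up(control_results, g)
    if (case_up && !ctrl_up) "case_only_increased"
    else if (case_up && ctrl_up) "both_increased"
    else "not_validated"
  }, "")
  data.frame(gene = genes, class = unname(cls), stringsAsFactors = FALSE)
}

#' Run the full qPCR validation layer
#'
#' @param ct Ct table covering both strains.
#' @param config A [cati_config()].
#' @param reference_tp,test_tps Contrast timepoints.
#' @return Object of class `qpcr_validation`: `tests` (the full
#'   [qpcr_test_table()]) and `classification` ([classify_validated()]).
#' @export
run_qpcr_validation <- function(ct, config = cati_config(),
                                reference_tp = 4, test_tps = c(8, 10)) {
  tests <- qpcr_test_table(ct, config, reference_tp, test_tps)
  cls <- classify_validated(tests[tests$strain == "case", , drop = FALSE],
                            tests[tests$strain == "control", , drop = FALSE],
                            config$alpha_test)
  structure(list(tests = tests, classification = cls, config = config),
            class = "qpcr_validation")
}

#' @export
print.qpcr_validation <- function(x, ...) {
  tab <- table(x$classification$class)
  cat("qPCR validation\n")
  cat(sprintf("  genes tested        : %d\n", nrow(x$classification)))
  for (k in c("case_only_increased", "both_increased", "not_validated")) {
    cat(sprintf("  %-20s: %d\n", k, if (k %in% names(tab)) tab[[k]] else 0L))
  }
  invisible(x)
}
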