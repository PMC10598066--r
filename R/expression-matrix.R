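#' Expression matrix with sample metadata
#'
#' Container for a normalized, linear-scale signal matrix (genes x samples)
#' together with the (strain, timepoint, replicate) metadata of every
#' sample column. Signals are expected to be post-normalization values on a
#' linear scale; use `delog = TRUE` in [read_expression_matrix()] if a file
#' stores log2 signals.
#'
#' @param signals Numeric matrix, genes in rows (unique rownames), samples
#'   in columns. All values must be non-negative and finite.
#' @param samples `data.frame` with columns `sample_id`, `strain`
#'   (`"case"` or `"control"`), `timepoint` (positive integer weeks) and
#'   `replicate` (positive integer); one row per signal column, matched by
#'   `sample_id` to `colnames(signals)`.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `signals` and `samples`.
#' @export
expr_matrix <- function(signals, samples) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "strain", "timepoint", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(rownames(signals)) && nrow(signals) > 0L) {
    stop("signal matrix must carry gene ids as rownames")
  }
  dup <- unique(rownames(signals)[duplicated(rownames(signals))])
  if (length(dup) > 0L) {
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in metadata")
  }
  if (ncol(signals) != nrow(samples) ||
      !setequal(colnames(signals), samples$sample_id)) {
    stop("signal columns and sample metadata do not match")
  }
  # align metadata rows to column order
  samples <- samples[match(colnames(signals), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$strain %in% c("case", "control"))) {
    stop("strain must be 'case' or 'control'")
  }
  samples$timepoint <- as.integer(samples$timepoint)
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$timepoint)) || any(samples$timepoint <= 0L)) {
    stop("timepoint must be a positive integer (weeks)")
  }
  if (any(is.na(samples$replicate)) || any(samples$replicate <= 0L)) {
    stop("replicate must be a positive integer")
  }
  if (nrow(signals) > 0L && ncol(signals) > 0L) {
    if (any(!is.finite(signals))) stop("signals must be finite")
    if (any(signals < 0)) stop("signals must be non-negative (linear scale)")
  }
  structure(list(signals = signals, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$samples$strain, x$samples$timepoint)
  cat(sprintf("Expression matrix: %d genes x %d samples\n",
              nrow(x$signals), ncol(x$signals)))
  if (ncol(x$signals) > 0L) {
    cat("Samples per (strain, week):\n")
    print(tab)
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$signals)

# sample ids like "case_4wk_1" <-> metadata rows
parse_sample_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(case|control)_([0-9]+)wk_([0-9]+)$", ids))
  bad <- ids[vapply(m, length, 1L) != 4L]
  if (length(bad) > 0L) return(NULL)
  data.frame(
    sample_id = ids,
    strain = vapply(m, `[`, "", 2L),
    timepoint = as.integer(vapply(m, `[`, "", 3L)),
    replicate = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

format_sample_ids <- function(samples) {
  sprintf("%s_%dwk_%d", samples$strain, samples$timepoint, samples$replicate)
}

#' Read an expression matrix from TSV
#'
#' The file must have a `gene_id` first column and one column per sample.
#' Sample metadata comes either from self-describing column names of the
#' form `"<strain>_<week>wk_<replicate>"` (e.g. `"case_8wk_2"`) or from a
#' sidecar table supplied via `samples`.
#'
#' @param path Path to a TSV file.
#' @param samples Optional sample metadata: a `data.frame` with columns
#'   `sample_id`, `strain`, `timepoint`, `replicate`, or the path of a TSV
#'   file with those columns. When `NULL`, metadata is parsed from the
#'   column names.
#' @param delog If `TRUE`, signals are interpreted as log2 values and
#'   transformed back to the linear scale (`2^x`) on read. There is no
#'   auto-detection; the caller must know the scale of the file.
#' @return An [expr_matrix()] object.
#' @export
read_expression_matrix <- function(path, samples = NULL, delog = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 1L || names(df)[1L] != "gene_id") {
    stop("expression file must start with a 'gene_id' column: ", path)
  }
  gene_ids <- as.character(df[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0L) {
    stop("duplicated gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  sig <- df[, -1L, drop = FALSE]
  for (j in seq_along(sig)) {
    v <- sig[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v))) {
        i <- which(is.na(vn) & !is.na(v))[1L]
        stop(sprintf("non-numeric signal at gene '%s', sample '%s'",
                     gene_ids[i], names(sig)[j]))
      }
      sig[[j]] <- vn
    }
  }
  signals <- as.matrix(sig)
  rownames(signals) <- gene_ids
  if (delog && length(signals) > 0L) signals <- 2^signals
  if (is.character(samples)) {
    samples <- utils::read.delim(samples, sep = "\t", stringsAsFactors = FALSE)
  }
  if (is.null(samples)) {
    samples <- parse_sample_ids(colnames(signals))
    if (is.null(samples)) {
      stop("sample columns are not self-describing ('<strain>_<week>wk_<rep>') ",
           "and no sample metadata was supplied")
    }
  }
  expr_matrix(signals, samples)
}

#' Write an expression matrix to TSV
#'
#' Columns are written under self-describing names
#' (`"<strain>_<week>wk_<replicate>"`) so that
#' [read_expression_matrix()] can recover the metadata without a sidecar.
#'
#' @param mat An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "expr_matrix"))
  out <- data.frame(gene_id = rownames(mat$signals), mat$signals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-1L] <- format_sample_ids(mat$samples)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
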