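#' Read an SSLP marker table
#'
#' @param path TSV file with columns `name`, `assembly`, `chrom`, `pos`
#'   (1-based).
#' @return A validated `data.frame` of markers. The same marker name may
#'   appear once per assembly; a duplicated (name, assembly) pair is an
#'   error.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  required <- c("name", "assembly", "chrom", "pos")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("marker table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$pos <- as.numeric(df$pos)
  if (any(is.na(df$pos)) || any(df$pos < 1)) stop("marker pos must be >= 1")
  key <- paste(df$name, df$assembly, sep = "@")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    stop("duplicated (name, assembly) marker(s): ", paste(dup, collapse = ", "))
  }
  df[, required]
}

get_marker <- function(markers, name, assembly) {
  hit <- markers[markers$name == name & markers$assembly == assembly, , drop = FALSE]
  if (nrow(hit) != 1L) {
    stop(sprintf("marker '%s' not found on assembly '%s'", name, assembly))
  }
  hit
}

#' Define a genomic locus interval
#'
#' Both endpoints are 1-based and inclusive, matching the convention of
#' SSLP-delimited linkage intervals ("from marker A to marker B").
#'
#' @param name Locus name (e.g. `"Cati1"`).
#' @param chrom Chromosome.
#' @param start,end Interval endpoints, `start <= end`.
#' @return A one-row `data.frame` with columns `name`, `chrom`, `start`,
#'   `end`; rows from several calls can be `rbind`-ed into a locus table.
#' @export
locus_interval <- function(name, chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 1L, length(end) == 1L)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid interval: start must be <= end")
  }
  data.frame(name = as.character(name), chrom = as.character(chrom),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Build a locus interval from two flanking markers
#'
#' @param markers Marker table ([read_marker_table()]).
#' @param name Locus name.
#' @param from,to Names of the two flanking markers (order-free; the
#'   smaller position becomes the start).
#' @param assembly Assembly on which to look the markers up.
#' @return A [locus_interval()].
#' @export
locus_from_markers <- function(markers, name, from, to, assembly) {
  a <- get_marker(markers, from, assembly)
  b <- get_marker(markers, to, assembly)
  if (a$chrom != b$chrom) {
    stop(sprintf("markers '%s' and '%s' lie on different chromosomes", from, to))
  }
  locus_interval(name, a$chrom, min(a$pos, b$pos), max(a$pos, b$pos))
}

#' Estimate a marker's position on another assembly by colinear offset
#'
#' When a marker has a published position on a source assembly only, its
#' position on a target assembly is estimated from an anchor marker placed
#' on both assemblies: the inter-marker base count is assumed conserved
#' (local colinearity, no inversion or indel between the two markers), so
#'
#' \deqn{\hat{pos}_{target}(m) = pos_{target}(anchor) -
#'       (pos_{source}(anchor) - pos_{source}(m))}
#'
#' The sign of the offset handles markers on either side of the anchor.
#' This is deliberately the naive distance-preserving estimate, not a
#' chain-file liftover.
#'
#' @param markers Marker table containing the marker on the source assembly
#'   and the anchor on both assemblies.
#' @param marker Name of the marker to place.
#' @param anchor Name of the anchor marker.
#' @param source,target Assembly labels.
#' @return A list with `name`, `chrom` (target-assembly chromosome of the
#'   anchor), `pos` (the estimate), `offset` (signed source-assembly
#'   distance marker - anchor) and `assumption` (documents colinearity).
#' @export
estimate_marker_position <- function(markers, marker, anchor, source, target) {
  m_src <- get_marker(markers, marker, source)
  a_src <- get_marker(markers, anchor, source)
  a_tgt <- get_marker(markers, anchor, target)
  if (m_src$chrom != a_src$chrom) {
    stop(sprintf("marker '%s' and anchor '%s' lie on different chromosomes in %s",
                 marker, anchor, source))
  }
  offset <- m_src$pos - a_src$pos
  list(
    name = marker,
    chrom = a_tgt$chrom,
    pos = a_tgt$pos + offset,
    offset = offset,
    assumption = "colinear: inter-marker base count conserved across assemblies"
  )
}
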