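# Shared format readers/writers. BED is 0-based half-open; TSVs are UTF-8
# with a header row and '.' for missing values. Validation reports offending
# line numbers rather than silently repairing records.

#' Read a BED feature track into a GRanges
#'
#' Columns: chrom, start, end, and an optional 4th column stored as the
#' `class` metadata column (feature/repeat class label). Coordinates are
#' validated (end > start) with line-numbered errors.
#'
#' @param path BED file path.
#' @return A [GenomicRanges::GRanges]; 0-based half-open input becomes
#'   1-based closed ranges internally.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3) stop("parse error: BED needs at least 3 columns in ", path)
  if (!is.numeric(df[[2]]) || !is.numeric(df[[3]]))
    stop("parse error: non-numeric coordinates in ", path)
  bad <- which(df[[3]] <= df[[2]])
  if (length(bad))
    stop("parse error: end <= start at line ", bad[1], " of ", path)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  if (ncol(df) >= 4) gr$class <- as.character(df[[4]])
  gr
}

#' Write a GRanges feature track as BED (0-based half-open)
#' @param track A GRanges, optionally with a `class` metadata column.
#' @param path Output path.
#' @export
write_features <- function(track, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(track)),
                   start = GenomicRanges::start(track) - 1L,
                   end = GenomicRanges::end(track))
  if (!is.null(track$class)) df$class <- track$class
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write junction calls to TSV ('.' for missing)
#' @param calls A `junction_calls` data.frame.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  out <- as.data.frame(calls)
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read junction calls written by [write_calls()]
#' @param path TSV path.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  if (!is.null(df$ins_seq)) df$ins_seq[is.na(df$ins_seq)] <- ""
  if (!is.null(df$ins_templated)) df$ins_templated <- as.logical(df$ins_templated)
  class(df) <- c("junction_calls", "data.frame")
  df
}

#' Read a bedGraph-like interval depth table
#'
#' Four columns (chrom, start, end, depth), 0-based half-open, validated
#' with line numbers.
#' @param path Input path.
#' @export
read_depth_intervals <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 4) stop("parse error: depth input needs 4 columns in ", path)
  names(df)[1:4] <- c("chrom", "start", "end", "depth")
  bad <- which(df$end <= df$start)
  if (length(bad)) stop("parse error: end <= start at line ", bad[1], " of ", path)
  if (any(df$depth < 0)) stop("parse error: negative depth in ", path)
  df[1:4]
}

#' Write a tidy TSV report table
#' @param x Data.frame.
#' @param path Output path.
#' @export
write_report_table <- function(x, path) {
  out <- as.data.frame(x)
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
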