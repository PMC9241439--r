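#' Per-chromosome fusion enrichment against size-normalized expectation
#'
#' Under the uniform null the expected junction count on a chromosome is
#' proportional to its length. Each chromosome is tested with a two-sided
#' exact binomial test of its observed count out of the total, with success
#' probability length/total length (the operational reading of per-chromosome
#' exact testing against size-normalized expected frequencies). Raw p-values
#' drive the comparison output; Holm-adjusted values are reported alongside.
#'
#' @param junctions Data.frame with columns `chrom` and `pos` (0-based), or a
#'   character vector of chromosome names.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return An `EnrichmentResult` data.frame: chrom, observed, expected,
#'   p_value, p_holm, test_name. Expected values sum to the total observed.
#' @export
chromosome_enrichment <- function(junctions, chrom_lengths) {
  chrom <- if (is.data.frame(junctions)) junctions$chrom else junctions
  if (!length(chrom)) stop("input error: no junctions")
  unknown <- setdiff(unique(chrom), names(chrom_lengths))
  if (length(unknown))
    stop("data error: junction on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  total <- length(chrom)
  obs <- table(factor(chrom, names(chrom_lengths)))
  pr <- chrom_lengths / sum(chrom_lengths)
  p <- vapply(seq_along(pr), function(i)
    binom_test_2sided(as.integer(obs[i]), total, pr[i]), numeric(1))
  data.frame(chrom = names(chrom_lengths),
             observed = as.integer(obs),
             expected = total * as.numeric(pr),
             p_value = p,
             p_holm = stats::p.adjust(p, "holm"),
             test_name = "exact_binomial_two_sided",
             row.names = NULL)
}

as_position_granges <- function(junctions) {
  GenomicRanges::GRanges(junctions$chrom,
                         IRanges::IRanges(junctions$pos + 1L, junctions$pos + 1L))
}

#' Coincidence of junction positions with a feature track
#'
#' A junction coincides with the track when its position falls inside at
#' least one interval (0-based half-open convention). Tracks carrying a
#' `class` metadata column additionally get per-class counts.
#'
#' @param junctions Data.frame with `chrom` and `pos` (0-based).
#' @param track A [GenomicRanges::GRanges] feature track (as produced by
#'   [read_features()] or [simulate_genome()]).
#' @return List: `n`, `coincident`, `proportion`, and `by_class` (data.frame
#'   or NULL).
#' @export
feature_coincidence <- function(junctions, track) {
  gr <- as_position_granges(junctions)
  hits <- GenomicRanges::countOverlaps(gr, track) > 0
  by_class <- NULL
  if (!is.null(track$class)) {
    ov <- GenomicRanges::findOverlaps(gr, track)
    cls <- track$class[S4Vectors::subjectHits(ov)]
    qh <- S4Vectors::queryHits(ov)
    counts <- vapply(split(qh, cls), function(ix) length(unique(ix)), integer(1))
    by_class <- data.frame(class = names(counts),
                           coincident = as.integer(counts),
                           proportion = as.integer(counts) / length(gr),
                           row.names = NULL)
  }
  list(n = length(gr), coincident = sum(hits),
       proportion = mean(hits), by_class = by_class)
}

#' Compare feature coincidence between two groups
#'
#' Fisher's exact test by default; the chi-squared test with Yates'
#' correction when either group is a large simulated set (where exact
#' enumeration is unnecessary and the legend convention switches).
#'
#' @param hit1,n1 Coincident count and total for group 1.
#' @param hit2,n2 Coincident count and total for group 2.
#' @param method `"fisher"` or `"yates"`, or `"auto"` to switch to Yates when
#'   either group exceeds `large_n`.
#' @param large_n Threshold for `"auto"`.
#' @return List with `p_value` and `test_name`.
#' @export
compare_coincidence <- function(hit1, n1, hit2, n2,
                                method = c("auto", "fisher", "yates"),
                                large_n = 1000L) {
  method <- match.arg(method)
  tb <- matrix(c(hit1, n1 - hit1, hit2, n2 - hit2), 2, byrow = TRUE)
  if (method == "auto")
    method <- if (max(n1, n2) > large_n) "yates" else "fisher"
  if (method == "fisher")
    list(p_value = fisher_exact_2x2(tb), test_name = "fisher_exact")
  else
    list(p_value = chi_squared_yates(tb)$p_value, test_name = "chi_squared_yates")
}
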