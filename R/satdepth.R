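# Satellite/rDNA content as normalized read depth over a labelled
# mini-reference of satellite regions.

#' Mean read depth per satellite region from interval depth input
#'
#' Consumes a bedGraph-like table of per-interval depths (sorted,
#' non-overlapping within a chromosome) and computes each region's mean
#' depth as sum(depth x covered bases) / region length; bases absent from
#' the depth input count as zero. Regions on chromosomes absent from the
#' depth input get mean 0 with a warning.
#'
#' @param depth Data.frame: chrom, start, end (0-based half-open), depth.
#' @param regions Data.frame: region_id, chrom, start, end, class.
#' @param sample_id Sample label.
#' @return A `DepthTable` data.frame.
#' @export
mean_region_depth <- function(depth, regions, sample_id = "sample") {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(depth)),
            all(c("region_id", "chrom", "start", "end", "class") %in% names(regions)))
  if (any(depth$end <= depth$start) || (nrow(regions) && any(regions$end <= regions$start)))
    stop("intervals must satisfy end > start")
  missing_chr <- setdiff(unique(regions$chrom), unique(depth$chrom))
  if (length(missing_chr))
    warning("no depth input for chromosome(s): ",
            paste(missing_chr, collapse = ", "), "; their regions get depth 0")
  means <- numeric(nrow(regions))
  if (nrow(depth)) {
    gr_d <- GenomicRanges::GRanges(depth$chrom,
                                   IRanges::IRanges(depth$start + 1L, depth$end))
    gr_r <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L, regions$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, gr_d))
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_r)[qi],
                                              IRanges::ranges(gr_d)[si]))
      contrib <- w * depth$depth[si]
      agg <- tapply(contrib, qi, sum)
      means[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  structure(data.frame(sample_id = sample_id,
                       region_id = regions$region_id,
                       class = regions$class,
                       mean_depth = means / (regions$end - regions$start),
                       normalized_depth = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("DepthTable", "data.frame"))
}

#' Normalize region depths to the sample mean
#'
#' Default mode divides by the unweighted mean of `mean_depth` over the
#' mini-reference regions, so the normalized values average exactly 1 (and
#' the operation is idempotent). Supplying `sample_mean` instead divides by
#' that externally determined genome-wide mean depth — the appropriate
#' denominator when the satellite classes under test may themselves be
#' expanded or contracted, which would otherwise contaminate the
#' normalizer.
#'
#' @param table A `DepthTable`.
#' @param sample_mean Optional externally supplied mean depth (positive).
#' @param weights Optional `"length"` with a `length_bp` column for
#'   length-weighted internal normalization.
#' @return The table with `normalized_depth` filled in.
#' @export
normalize_to_sample_mean <- function(table, sample_mean = NULL, weights = NULL) {
  stopifnot(inherits(table, "data.frame"), "mean_depth" %in% names(table))
  if (all(table$mean_depth == 0)) stop("normalization error: all depths are zero")
  denom <- if (!is.null(sample_mean)) {
    stopifnot(sample_mean > 0)
    sample_mean
  } else if (identical(weights, "length")) {
    stopifnot("length_bp" %in% names(table))
    sum(table$mean_depth * table$length_bp) / sum(table$length_bp)
  } else {
    mean(table$mean_depth)
  }
  table$normalized_depth <- table$mean_depth / denom
  table
}

#' Per-region and per-class log2 depth ratios between mutant and wild type
#'
#' Ratios are computed on normalized depths for shared regions; regions
#' where the wild-type normalized depth is zero are excluded with a warning
#' (and counted). The per-class summary is the unweighted mean of its
#' regions' ratios, so swapping the samples negates every value.
#'
#' @param mutant,wt Normalized `DepthTable`s sharing region_ids.
#' @return List: `per_region` (region_id, class, log2_ratio) and `per_class`
#'   (class, mean_log2_ratio, n, n_excluded).
#' @export
class_log2_ratio <- function(mutant, wt) {
  stopifnot(!any(is.na(mutant$normalized_depth)),
            !any(is.na(wt$normalized_depth)))
  shared <- intersect(mutant$region_id, wt$region_id)
  if (!length(shared)) stop("no shared regions between tables")
  m <- mutant[match(shared, mutant$region_id), ]
  w <- wt[match(shared, wt$region_id), ]
  bad <- w$normalized_depth == 0
  if (any(bad))
    warning(sum(bad), " region(s) excluded: zero wild-type depth")
  keep <- !bad
  per_region <- data.frame(region_id = shared[keep], class = m$class[keep],
                           log2_ratio = log2(m$normalized_depth[keep] /
                                             w$normalized_depth[keep]))
  excl <- tapply(bad, m$class, sum)
  agg <- split(per_region$log2_ratio, per_region$class)
  per_class <- data.frame(class = names(agg),
                          mean_log2_ratio = vapply(agg, mean, numeric(1)),
                          n = lengths(agg),
                          n_excluded = as.integer(excl[names(agg)]),
                          row.names = NULL)
  list(per_region = per_region, per_class = per_class)
}

#' Paired rank test of mutant vs wild-type depths for one satellite class
#'
#' Wilcoxon matched-pairs signed-rank test on the paired normalized depths
#' of the class's shared regions (delegating to [wilcoxon_signed_rank()]).
#' Fewer than 5 shared regions is indeterminate.
#'
#' @param mutant,wt Normalized `DepthTable`s.
#' @param class Satellite class label to test.
#' @return List with `class`, `n_pairs`, `p_value` (NA when indeterminate).
#' @export
paired_class_test <- function(mutant, wt, class) {
  m <- mutant[mutant$class == class, ]
  w <- wt[wt$class == class, ]
  shared <- intersect(m$region_id, w$region_id)
  if (length(shared) < 5) {
    warning("fewer than 5 shared regions for class ", class, ": indeterminate")
    return(list(class = class, n_pairs = length(shared), p_value = NA_real_))
  }
  mv <- m$normalized_depth[match(shared, m$region_id)]
  wv <- w$normalized_depth[match(shared, w$region_id)]
  p <- wilcoxon_signed_rank(mv, wv)
  list(class = class, n_pairs = length(shared), p_value = p)
}
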