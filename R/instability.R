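# Whole-genome instability analyses: copy-number background subtraction and
# segmentation, cohort-unique segments, SV/fusion proximity, and VAF-based
# clonality.

check_cn_profile <- function(p) {
  stopifnot(is.data.frame(p),
            all(c("chrom", "start", "end", "log2_ratio") %in% names(p)))
  if (any(!is.finite(p$log2_ratio))) stop("non-finite log2 ratio in profile")
  invisible(p)
}

#' Subtract a reference copy-number profile from a target profile
#'
#' Per-bin difference of log2 ratios (e.g. parental subtracted from early
#' crisis, or late from early). Bin grids must be identical; there is no
#' silent re-binning.
#'
#' @param target,reference CN profiles: data.frames with `chrom`, `start`,
#'   `end` (0-based half-open bins) and `log2_ratio`.
#' @return The differential profile, with attribute `subtraction` recording
#'   the pair of sample ids when present.
#' @export
background_subtract <- function(target, reference) {
  check_cn_profile(target); check_cn_profile(reference)
  if (nrow(target) != nrow(reference) ||
      !all(target$chrom == reference$chrom) ||
      !all(target$start == reference$start) ||
      !all(target$end == reference$end))
    stop("input error: bin grids differ between target and reference")
  out <- target
  out$log2_ratio <- target$log2_ratio - reference$log2_ratio
  attr(out, "subtraction") <- c(target = target$sample_id[1] %||% NA,
                                reference = reference$sample_id[1] %||% NA)
  out
}

#' Segment a copy-number profile into gain/loss segments
#'
#' Maximal runs of at least `min_bins` consecutive bins (within a
#' chromosome) whose |log2 ratio| meets `threshold` with a consistent sign
#' become segments.
#'
#' @param profile A CN profile data.frame (sorted bins).
#' @param threshold Minimum |log2| per bin.
#' @param min_bins Minimum run length.
#' @return Data.frame of segments: chrom, start, end, direction (gain/loss),
#'   mean_log2, n_bins.
#' @export
segment_profile <- function(profile, threshold = 0.3, min_bins = 10L) {
  check_cn_profile(profile)
  stopifnot(threshold > 0, min_bins >= 1)
  segs <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    state <- ifelse(p$log2_ratio >= threshold, 1L,
                    ifelse(p$log2_ratio <= -threshold, -1L, 0L))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] == 0L || r$lengths[i] < min_bins) next
      ix <- starts[i]:ends[i]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = p$start[starts[i]], end = p$end[ends[i]],
        direction = if (r$values[i] > 0) "gain" else "loss",
        mean_log2 = mean(p$log2_ratio[ix]), n_bins = length(ix),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      mean_log2 = numeric(0), n_bins = integer(0)))
  do.call(rbind, segs)
}

reciprocal_overlap_frac <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Identify cohort-unique copy-number segments
#'
#' A segment is unique to its sample iff no other sample carries a
#' same-direction segment with reciprocal overlap at or above the cutoff.
#' The decision is direction-aware: a gain and a loss over the same
#' coordinates are both unique.
#'
#' @param cohort Named list of per-sample segment data.frames (from
#'   [segment_profile()]).
#' @param reciprocal_overlap Reciprocal-overlap cutoff in (0, 1].
#' @return The cohort list with a logical `unique` column added per segment.
#' @export
unique_segments <- function(cohort, reciprocal_overlap = 0.5) {
  stopifnot(reciprocal_overlap > 0, reciprocal_overlap <= 1)
  nms <- names(cohort) %||% as.character(seq_along(cohort))
  lapply(stats::setNames(seq_along(cohort), nms), function(i) {
    me <- cohort[[i]]
    if (!nrow(me)) { me$unique <- logical(0); return(me) }
    others <- do.call(rbind, cohort[-i])
    me$unique <- vapply(seq_len(nrow(me)), function(j) {
      if (is.null(others) || !nrow(others)) return(TRUE)
      cand <- others[others$chrom == me$chrom[j] &
                     others$direction == me$direction[j], , drop = FALSE]
      if (!nrow(cand)) return(TRUE)
      all(reciprocal_overlap_frac(me$start[j], me$end[j],
                                  cand$start, cand$end) < reciprocal_overlap)
    }, logical(1))
    me
  })
}

#' Fractions of fusion junctions near unique SV breakpoints
#'
#' For each distance bin d, the fraction of genomic fusion junctions whose
#' nearest unique structural-variant breakpoint on the same chromosome lies
#' within d bp. Translocations contribute both breakpoints independently;
#' breakpoints on other chromosomes are infinitely far.
#'
#' @param svs Data.frame of SV records: sv_id, type (DEL/INV/DUP/TRA/INS),
#'   chrom1, pos1, chrom2, pos2, unique (logical).
#' @param junctions Data.frame with `chrom` and `pos`.
#' @param distance_bins_bp Increasing distances in bp
#'   (default 0.1, 1, 5, 10 Mb).
#' @return Data.frame: distance_bp, n_within, fraction (monotone
#'   non-decreasing).
#' @export
sv_fusion_proximity <- function(svs, junctions,
                                distance_bins_bp = c(1e5, 1e6, 5e6, 1e7)) {
  stopifnot(all(diff(distance_bins_bp) > 0))
  n <- nrow(junctions)
  if (n == 0) stop("input error: no junctions")
  bp <- if (nrow(svs)) {
    u <- svs[as.logical(svs$unique), , drop = FALSE]
    rbind(data.frame(chrom = u$chrom1, pos = u$pos1),
          data.frame(chrom = u$chrom2, pos = u$pos2))
  } else data.frame(chrom = character(0), pos = numeric(0))
  bp <- bp[!is.na(bp$chrom) & !is.na(bp$pos), , drop = FALSE]
  nearest <- vapply(seq_len(n), function(i) {
    cand <- bp$pos[bp$chrom == junctions$chrom[i]]
    if (!length(cand)) return(Inf)
    min(abs(cand - junctions$pos[i]))
  }, numeric(1))
  data.frame(distance_bp = distance_bins_bp,
             n_within = vapply(distance_bins_bp,
                               function(d) sum(nearest <= d), integer(1)),
             fraction = vapply(distance_bins_bp,
                               function(d) mean(nearest <= d), numeric(1)))
}

#' Classify clonality from a variant-allele-frequency table
#'
#' A clone whose median unique-variant VAF shows a considerable shift below
#' 0.5 (the heterozygous expectation in a monoclonal population) is called
#' polyclonal. The threshold is configurable and reported with every
#' verdict; below the variant floor the verdict is indeterminate.
#'
#' @param vaf_table Data.frame with a `vaf` column (and optional sample_id).
#' @param median_threshold Polyclonality cutoff on the median VAF, in
#'   (0, 0.5).
#' @param min_variants Minimum variants required for a verdict.
#' @return A `ClonalityCall` data.frame: sample_id, n_variants, median_vaf,
#'   threshold, verdict.
#' @export
classify_clonality <- function(vaf_table, median_threshold = 0.4,
                               min_variants = 20L) {
  stopifnot(median_threshold > 0, median_threshold < 0.5)
  v <- vaf_table$vaf
  if (any(v < 0 | v > 1)) stop("input error: VAF outside [0,1]")
  med <- stats::median(v)
  verdict <- if (length(v) < min_variants) {
    warning("fewer than ", min_variants, " variants: verdict indeterminate")
    "indeterminate"
  } else if (med < median_threshold) "polyclonal" else "monoclonal"
  data.frame(sample_id = vaf_table$sample_id[1] %||% NA_character_,
             n_variants = length(v), median_vaf = med,
             threshold = median_threshold, verdict = verdict,
             stringsAsFactors = FALSE)
}
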