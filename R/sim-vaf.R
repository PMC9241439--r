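#' Simulate a variant-allele-frequency table
#'
#' Emulates clonality assessment from unique single-nucleotide variant VAFs.
#' A monoclonal population (single subclone fraction 1.0) carries
#' heterozygous variants with expected VAF 0.5; each subclone's private
#' variants have expected VAF = fraction/2. Read support is binomially
#' sampled at the stated depth.
#'
#' @param n_variants Number of variants (>= 1).
#' @param subclone_fractions Numeric vector of subclone cell fractions
#'   summing to at most 1. Variants are assigned to subclones uniformly.
#' @param depth Sequencing depth per variant (positive integer).
#' @param seed Seed.
#' @param sample_id Sample label.
#' @return A `VAFTable` data.frame: sample_id, chrom, pos, ref_count,
#'   alt_count, vaf.
#' @export
simulate_vaf_table <- function(n_variants, subclone_fractions = 1.0,
                               depth = 100L, seed = 1L,
                               sample_id = "sample") {
  if (depth < 1) stop("configuration error: depth must be positive")
  if (n_variants < 1) stop("configuration error: n_variants must be positive")
  if (any(subclone_fractions <= 0) || sum(subclone_fractions) > 1 + 1e-9)
    stop("configuration error: subclone fractions must be positive and sum to <= 1")
  with_stream_seed(seed, "vaf", {
    sub <- sample.int(length(subclone_fractions), n_variants, replace = TRUE)
    true_vaf <- subclone_fractions[sub] / 2
    alt <- stats::rbinom(n_variants, depth, true_vaf)
    data.frame(sample_id = sample_id,
               chrom = paste0("chr", sample.int(5L, n_variants, replace = TRUE)),
               pos = sample.int(5e7, n_variants, replace = TRUE) - 1L,
               ref_count = depth - alt,
               alt_count = alt,
               vaf = alt / depth,
               stringsAsFactors = FALSE)
  })
}

#' Simulate per-region read depths with class-specific scalings
#'
#' Region depths are gamma-distributed with mean
#' `base_depth * scaling(class)` and coefficient of variation `dispersion`
#' (exactly the mean when `dispersion = 0`), emulating satellite content
#' expansion or contraction as a read-depth proxy.
#'
#' @param regions Data.frame with `region_id` and `class` columns (e.g. from
#'   [satellite_region_set()]).
#' @param class_scalings Named vector: class -> positive multiplier. Classes
#'   absent from the vector default to 1.
#' @param base_depth Genome-wide mean depth (positive).
#' @param dispersion Coefficient of variation of region depth.
#' @param seed Seed.
#' @param sample_id Sample label.
#' @return A `DepthTable` data.frame: sample_id, region_id, class,
#'   mean_depth, normalized_depth (NA until normalization).
#' @export
simulate_region_depths <- function(regions, class_scalings = numeric(0),
                                   base_depth = 30, dispersion = 0.05,
                                   seed = 1L, sample_id = "sample") {
  stopifnot(is.data.frame(regions), all(c("region_id", "class") %in% names(regions)))
  if (base_depth <= 0 || dispersion < 0)
    stop("configuration error: base_depth must be positive, dispersion non-negative")
  if (length(class_scalings) && any(class_scalings <= 0))
    stop("configuration error: non-positive class scaling")
  sc <- rep(1, nrow(regions))
  hit <- regions$class %in% names(class_scalings)
  sc[hit] <- class_scalings[regions$class[hit]]
  mu <- base_depth * sc
  with_stream_seed(seed, paste0("depth:", sample_id), {
    depth <- if (dispersion == 0) mu else
      stats::rgamma(nrow(regions), shape = 1 / dispersion^2,
                    scale = mu * dispersion^2)
    structure(data.frame(sample_id = sample_id,
                         region_id = regions$region_id,
                         class = regions$class,
                         mean_depth = depth,
                         normalized_depth = NA_real_,
                         stringsAsFactors = FALSE),
              class = c("DepthTable", "data.frame"))
  })
}
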