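#' Configuration for a toy genome with feature tracks
#'
#' A desk-scale stand-in for a reference genome: a handful of small
#' chromosomes of random sequence plus labelled interval tracks (genes,
#' fragile sites, and RepeatMasker-style repeat classes). The deliberately
#' unequal chromosome lengths exercise the size-normalized chromosome
#' enrichment analysis.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param gene_coverage,fragile_coverage Target fraction of each chromosome
#'   covered by the gene / fragile-site tracks.
#' @param repeat_coverage Named numeric vector: repeat class -> target
#'   coverage fraction. Class names follow the T2T/RepeatMasker vocabulary
#'   (ALR, TAR, satellite, LINE, SINE, LTR, STR, DNA, ...).
#' @param mean_feature_bp Mean feature length (exponential) for all tracks.
#' @param seed Non-negative integer seed.
#' @export
sim_genome_config <- function(chrom_lengths = c(chr1 = 50000L, chr2 = 40000L,
                                                chr3 = 30000L, chr4 = 20000L,
                                                chr5 = 10000L),
                              gene_coverage = 0.30,
                              fragile_coverage = 0.05,
                              repeat_coverage = c(ALR = 0.02, TAR = 0.01,
                                                  satellite = 0.02, LINE = 0.10,
                                                  SINE = 0.08, LTR = 0.04,
                                                  STR = 0.02, DNA = 0.03),
                              mean_feature_bp = 600,
                              seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("configuration error: chrom_lengths must be a named vector of positive lengths")
  if (sum(repeat_coverage) > 0.9 || any(repeat_coverage < 0))
    stop("configuration error: repeat coverages must be non-negative and sum below 0.9")
  structure(list(chrom_lengths = chrom_lengths,
                 gene_coverage = gene_coverage,
                 fragile_coverage = fragile_coverage,
                 repeat_coverage = repeat_coverage,
                 mean_feature_bp = mean_feature_bp,
                 seed = as.integer(seed)),
            class = "sim_genome_config")
}

# place non-overlapping intervals on one chromosome until `target_bp` covered;
# returns a data.frame of 0-based half-open intervals
place_intervals <- function(chrom, len, target_bp, mean_bp, occupied) {
  starts <- integer(0); ends <- integer(0)
  covered <- 0; tries <- 0
  while (covered < target_bp && tries < 5000L) {
    tries <- tries + 1L
    w <- max(50L, min(round(stats::rexp(1, 1 / mean_bp)) + 50L, len %/% 4L))
    s <- sample.int(len - w, 1L) - 1L
    e <- s + w
    clash <- any(s < occupied$end & e > occupied$start) ||
      (length(starts) && any(s < ends & e > starts))
    if (!clash) {
      starts <- c(starts, s); ends <- c(ends, e)
      covered <- covered + w
    }
  }
  data.frame(chrom = rep(chrom, length(starts)), start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Simulate a toy genome with gene, fragile-site and repeat tracks
#'
#' @param config A [sim_genome_config()].
#' @return A `SimGenome`: list with `seq` (named character), `chrom_lengths`,
#'   and `tracks` — a named list of [GenomicRanges::GRanges] (`genes`,
#'   `fragile_sites`, `repeats`; the repeats track carries a `class` metadata
#'   column). All intervals are 0-based half-open internally and stored as
#'   1-based closed GRanges.
#' @export
simulate_genome <- function(config = sim_genome_config()) {
  if (!inherits(config, "sim_genome_config"))
    stop("configuration error: expected a sim_genome_config object")
  with_stream_seed(config$seed, "genome", {
    cl <- config$chrom_lengths
    seqs <- vapply(cl, random_dna, character(1))
    none <- data.frame(start = integer(0), end = integer(0))
    mk_track <- function(cov_by_class) {
      out <- list()
      for (chrom in names(cl)) {
        occ <- none
        for (klass in names(cov_by_class)) {
          iv <- place_intervals(chrom, cl[[chrom]],
                                round(cov_by_class[[klass]] * cl[[chrom]]),
                                config$mean_feature_bp, occ)
          if (nrow(iv)) {
            iv$class <- klass
            out[[length(out) + 1L]] <- iv
            occ <- rbind(occ, iv[c("start", "end")])
          }
        }
      }
      df <- if (length(out)) do.call(rbind, out) else
        data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   class = character(0))
      gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start + 1L, df$end),
                                   class = df$class)
      GenomicRanges::sort(gr)
    }
    tracks <- list(
      genes = mk_track(c(gene = config$gene_coverage)),
      fragile_sites = mk_track(c(fragile_site = config$fragile_coverage)),
      repeats = mk_track(config$repeat_coverage)
    )
    structure(list(seq = seqs, chrom_lengths = cl, tracks = tracks,
                   config = config),
              class = "SimGenome")
  })
}

#' @export
print.SimGenome <- function(x, ...) {
  cat("SimGenome:", length(x$chrom_lengths), "chromosomes,",
      sum(x$chrom_lengths), "bp total\n")
  for (tr in names(x$tracks))
    cat("  track", tr, ":", length(x$tracks[[tr]]), "intervals\n")
  invisible(x)
}

#' Build a labelled satellite mini-reference region set
#'
#' Emulates the satellite/rDNA regions extracted from a telomere-to-telomere
#' assembly into a mini reference for read-depth quantification. Regions are
#' laid out head to tail on one virtual contig per class; only their lengths
#' and class labels matter to the depth analyses.
#'
#' @param classes Character vector of satellite class labels.
#' @param n_per_class Number of regions per class.
#' @param region_bp Mean region length in bp (uniform between 0.5x and 1.5x).
#' @param seed Seed for the region-length draw.
#' @return A data.frame with columns region_id, chrom, start, end (0-based
#'   half-open), class.
#' @export
satellite_region_set <- function(classes = c("monomer", "HOR", "dHOR",
                                             "HSAT1", "HSAT2", "HSAT3",
                                             "HSAT4", "HSAT5", "bSAT",
                                             "gSAT", "censat", "CT", "rDNA"),
                                 n_per_class = 50L, region_bp = 5000L,
                                 seed = 1L) {
  stopifnot(n_per_class >= 1, region_bp >= 10)
  with_stream_seed(seed, "satregions", {
    out <- lapply(classes, function(klass) {
      w <- round(stats::runif(n_per_class, 0.5 * region_bp, 1.5 * region_bp))
      e <- cumsum(w)
      data.frame(region_id = sprintf("%s_%03d", klass, seq_len(n_per_class)),
                 chrom = paste0("sat_", klass),
                 start = c(0L, e[-length(e)]), end = e,
                 class = klass, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
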