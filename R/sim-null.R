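#' Simulate null junction positions uniform over the usable genome
#'
#' Draws positions uniformly over all non-excluded bases: chromosomes receive
#' counts in proportion to their usable length (in expectation) and positions
#' within a chromosome are uniform over the bases outside the excluded
#' intervals. Used to build the simulated fusion dataset against which
#' feature coincidence of observed junctions is compared.
#'
#' @param n Number of positions (>= 1).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param excluded Optional [GenomicRanges::GRanges] of intervals to avoid.
#' @param seed Seed.
#' @return Data.frame with `chrom` and 0-based `pos`.
#' @export
simulate_null_junction_positions <- function(n, chrom_lengths, excluded = NULL,
                                             seed = 1L) {
  stopifnot(n >= 1, length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  allowed <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    full <- IRanges::IRanges(1L, len)
    if (is.null(excluded) || length(excluded) == 0L) return(full)
    ex <- excluded[GenomicRanges::seqnames(excluded) == ch]
    if (length(ex) == 0L) return(full)
    exr <- IRanges::reduce(IRanges::ranges(ex))
    if (any(IRanges::start(exr) < 1L) || any(IRanges::end(exr) > len))
      stop("excluded intervals outside chromosome bounds on ", ch)
    IRanges::setdiff(full, exr)
  })
  names(allowed) <- names(chrom_lengths)
  usable <- vapply(allowed, function(ir) sum(IRanges::width(ir)), numeric(1))
  if (sum(usable) == 0)
    stop("infeasible: excluded intervals cover the entire genome")
  with_stream_seed(seed, "nullpos", {
    chs <- sample(names(chrom_lengths), n, replace = TRUE,
                  prob = usable / sum(usable))
    pos <- integer(n)
    for (ch in unique(chs)) {
      ix <- which(chs == ch)
      ir <- allowed[[ch]]
      w <- IRanges::width(ir)
      off <- sample.int(sum(w), length(ix), replace = TRUE)  # 1..usable
      cw <- cumsum(w)
      block <- findInterval(off - 1L, c(0L, cw[-length(cw)] + 0L), rightmost.closed = FALSE)
      # map the offset within concatenated allowed bases back to coordinates
      prev <- c(0L, cw[-length(cw)])
      pos[ix] <- IRanges::start(ir)[block] - 1L + (off - prev[block]) - 1L
    }
    data.frame(chrom = chs, pos = pos, stringsAsFactors = FALSE)
  })
}
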