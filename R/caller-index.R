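# Reference store and seed index for the junction caller.
#
# All references (panel members and toy-genome chromosomes) are held in one
# store with precomputed forward and reverse-complement character vectors;
# arm alignments are computed on the oriented strings and converted back to
# original coordinates only when a call is emitted.

build_refstore <- function(panel, genome = NULL) {
  stopifnot(inherits(panel, "ReferencePanel"))
  nm_p <- panel$entries$name
  seqs <- panel$seq[nm_p]
  is_panel <- rep(TRUE, length(nm_p))
  family <- panel$entries$family
  origin <- panel$entries$telomere_origin
  side <- panel$entries$telomere_side
  if (!is.null(genome)) {
    if (any(names(genome$seq) %in% nm_p))
      stop("panel member and chromosome names must not collide")
    seqs <- c(seqs, genome$seq)
    is_panel <- c(is_panel, rep(FALSE, length(genome$seq)))
    family <- c(family, rep(NA_character_, length(genome$seq)))
    origin <- c(origin, rep(NA_integer_, length(genome$seq)))
    side <- c(side, rep(NA_character_, length(genome$seq)))
  }
  rc <- vapply(seqs, revcomp, character(1))
  list(names = names(seqs),
       seq = seqs, rc = rc,
       chars_fwd = lapply(seqs, seq_chars),
       chars_rev = lapply(rc, seq_chars),
       len = nchar(unname(seqs)),
       is_panel = is_panel, family = family,
       origin = origin, side = side)
}

oriented_chars <- function(store, ref_id, strand) {
  if (strand == "+") store$chars_fwd[[ref_id]] else store$chars_rev[[ref_id]]
}

oriented_string <- function(store, ref_id, strand) {
  if (strand == "+") store$seq[[ref_id]] else store$rc[[ref_id]]
}

#' Build a k-mer seed index over a subtelomere panel (and toy genome)
#'
#' Indexes every k-mer of every reference on both strands; repeated k-mers
#' (e.g. those shared by homologous family members) retain all their
#' positions. Positions are stored on the oriented (strand-specific) string.
#'
#' @param panel A `ReferencePanel`.
#' @param genome Optional `SimGenome` whose chromosomes are indexed too.
#' @param k Seed length, 8..31 and no longer than the shortest reference.
#' @return A `SeedIndex` object used by [align_arms()] and [call_junctions()].
#' @export
index_panel <- function(panel, genome = NULL, k = 15L) {
  if (k < 8 || k > 31)
    stop("configuration error: k must lie in [8, 31]")
  store <- build_refstore(panel, genome)
  if (k > min(store$len))
    stop("configuration error: k (", k, ") exceeds the shortest reference (",
         min(store$len), " bp)")
  ref_id <- integer(0); pos <- integer(0); strand <- integer(0)
  kmers <- character(0)
  for (ri in seq_along(store$names)) {
    for (st in 1:2) {
      s <- if (st == 1L) store$seq[[ri]] else store$rc[[ri]]
      starts <- kmer_starts(nchar(s), k)
      km <- substring(s, starts, starts + k - 1L)
      keep <- !grepl("N", km, fixed = TRUE)
      km <- km[keep]; st_pos <- starts[keep]
      n <- length(km)
      ref_id <- c(ref_id, rep.int(ri, n))
      pos <- c(pos, st_pos)
      strand <- c(strand, rep.int(st, n))
      kmers <- c(kmers, km)
    }
  }
  env <- list2env(split(seq_along(kmers), kmers), hash = TRUE)
  structure(list(k = as.integer(k), env = env,
                 ref_id = ref_id, pos = pos, strand = strand,
                 store = store),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  cat("SeedIndex: k =", x$k, ",", length(x$ref_id), "indexed positions over",
      length(x$store$names), "references (both strands)\n")
  invisible(x)
}

#' Look up one k-mer in a seed index
#'
#' @param index A `SeedIndex`.
#' @param kmer Character scalar of length `k`.
#' @return Data.frame of hits: reference name, 1-based oriented offset,
#'   strand (`+`/`-`).
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "SeedIndex"), nchar(kmer) == index$k)
  ids <- index$env[[kmer]]
  if (is.null(ids))
    return(data.frame(ref = character(0), pos = integer(0), strand = character(0)))
  data.frame(ref = index$store$names[index$ref_id[ids]],
             pos = index$pos[ids],
             strand = c("+", "-")[index$strand[ids]],
             stringsAsFactors = FALSE)
}
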