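# Low-level sequence helpers shared by the simulator and the caller.
# Sequences travel internally as plain character scalars (one string per
# reference); Biostrings is used at the FASTA/FASTQ boundary.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of character DNA sequences
#' @param x Character vector of sequences over ACGTN.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a sequence into a character vector of single bases (1-based indexing)
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# introduce substitutions at per-base rate `rate`; substituted bases always
# differ from the original so the realized mismatch rate equals `rate`
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- seq_chars(s)
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# per-base identity of two equal-length strings
seq_identity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

# all k-mer start positions (1-based) of a string, optionally strided
kmer_starts <- function(len, k, stride = 1L) {
  if (len < k) return(integer(0))
  seq.int(1L, len - k + 1L, by = stride)
}
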