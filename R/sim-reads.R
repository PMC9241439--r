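#' Render paired amplicon reads from simulated fusion events
#'
#' Reconstructs each fusion amplicon from the event's arm coordinates (the
#' intra-chromosomal class yields fold-back palindromes, with the second arm
#' reverse-complemented) and emits paired reads. Read 1 is placed so it spans
#' the junction with at least `min_arm_read` bases on each side; read 2 is
#' taken from the far end of a fragment of length `fragment_bp` and
#' reverse-complemented. Substitution errors (no indels) are applied at
#' `error_rate` per base; an erroneous base always differs from the original.
#'
#' Events whose amplicon cannot accommodate the requested read length are
#' skipped and recorded in the `skipped` table, never silently dropped.
#'
#' @param events A `fusion_truth` table from [simulate_fusion_events()].
#' @param panel,genome The references used to simulate `events`.
#' @param read_len Read length (>= 50).
#' @param error_rate Per-base substitution rate in [0, 0.05].
#' @param seed Seed for placement and errors.
#' @param pairs_per_event Read pairs emitted per event.
#' @param flank_bp Amplicon flank retained on each side of the junction.
#' @param fragment_bp Sequenced fragment length.
#' @param min_arm_read Minimum read bases on each side of the junction in R1.
#' @return An `amplicon_reads` object: list with `r1`, `r2` (named character
#'   vectors of sequences), `reads` (read-to-event truth links), `truth`
#'   (the events), `amplicons`, `junction_at` (1-based junction offsets), and
#'   `skipped`.
#' @export
render_amplicon_reads <- function(events, panel, genome = NULL,
                                  read_len = 150L, error_rate = 0,
                                  seed = 1L, pairs_per_event = 1L,
                                  flank_bp = 250L, fragment_bp = 300L,
                                  min_arm_read = 50L) {
  stopifnot(inherits(events, "data.frame"), inherits(panel, "ReferencePanel"))
  if (read_len < 50) stop("read_len must be >= 50")
  if (error_rate < 0 || error_rate > 0.05) stop("error_rate must lie in [0, 0.05]")
  if (fragment_bp < read_len) stop("fragment_bp must be >= read_len")

  rev_str <- vapply(panel$seq, revcomp, character(1))
  if (!is.null(genome)) grev_str <- vapply(genome$seq, revcomp, character(1))

  with_stream_seed(seed, "reads", {
    amps <- character(nrow(events)); junc <- integer(nrow(events))
    skipped <- list()
    r1 <- character(0); r2 <- character(0)
    link <- list()
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      fa_str <- panel$seq[[ev$ref_a]]
      fb_str <- if (ev$fusion_class == "genomic") {
        if (ev$strand_b == "+") genome$seq[[ev$ref_b]] else grev_str[[ev$ref_b]]
      } else rev_str[[ev$ref_b]]
      p <- ev$.p; x <- ev$.x
      fa <- min(p, flank_bp)
      fb <- min(nchar(fb_str) - x, flank_bp)
      a_part <- substr(fa_str, p - fa + 1L, p)
      b_part <- substr(fb_str, x + 1L, x + fb)
      amp <- paste0(a_part, ev$ins_seq, b_part)
      amps[i] <- amp; ell <- nchar(ev$ins_seq)
      j <- fa  # junction: last base of arm A within the amplicon (1-based)
      junc[i] <- j
      alen <- nchar(amp)
      lo <- max(1L, j + ell + min_arm_read + ev$mh_len - read_len + 1L)
      hi <- min(j - min_arm_read + 1L, alen - read_len + 1L)
      if (alen < read_len || lo > hi) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(event_id = ev$event_id,
                     reason = if (alen < read_len) "read_len_exceeds_amplicon"
                              else "junction_too_close_to_amplicon_end")
        next
      }
      for (pr in seq_len(pairs_per_event)) {
        s1 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        e2 <- min(alen, s1 + fragment_bp - 1L)
        id <- sprintf("%s_p%d", ev$event_id, pr)
        r1[[id]] <- substr(amp, s1, s1 + read_len - 1L)
        r2[[id]] <- revcomp(substr(amp, e2 - read_len + 1L, e2))
        link[[length(link) + 1L]] <-
          data.frame(read_id = id, event_id = ev$event_id,
                     r1_start = s1, r2_end = e2)
      }
    }
    if (error_rate > 0) {
      apply_err <- function(v) {
        ch <- strsplit(v, "", fixed = TRUE)
        vapply(ch, function(x) {
          hit <- which(stats::runif(length(x)) < error_rate)
          for (h in hit) x[h] <- sample(setdiff(BASES, x[h]), 1L)
          paste(x, collapse = "")
        }, character(1))
      }
      nm1 <- names(r1); nm2 <- names(r2)
      r1 <- stats::setNames(apply_err(r1), nm1)
      r2 <- stats::setNames(apply_err(r2), nm2)
    }
    structure(list(
      r1 = r1, r2 = r2,
      reads = if (length(link)) do.call(rbind, link) else
        data.frame(read_id = character(0), event_id = character(0),
                   r1_start = integer(0), r2_end = integer(0)),
      truth = events, amplicons = stats::setNames(amps, events$event_id),
      junction_at = stats::setNames(junc, events$event_id),
      skipped = if (length(skipped)) do.call(rbind, skipped) else
        data.frame(event_id = character(0), reason = character(0)),
      read_len = as.integer(read_len)),
      class = "amplicon_reads")
  })
}

#' @export
print.amplicon_reads <- function(x, ...) {
  cat("amplicon_reads:", length(x$r1), "read pairs from",
      nrow(x$truth), "events (", nrow(x$skipped), "skipped )\n")
  invisible(x)
}

#' Write paired reads to FASTQ (Phred+33)
#' @param reads An `amplicon_reads` object or list with `r1`, `r2` named
#'   character vectors.
#' @param r1_path,r2_path Output FASTQ paths.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  wr <- function(v, path) {
    ds <- Biostrings::DNAStringSet(v)
    q <- Biostrings::BStringSet(strrep("I", nchar(v)))
    names(ds) <- names(v)
    Biostrings::writeXStringSet(ds, path, format = "fastq", qualities = q)
  }
  wr(reads$r1, r1_path)
  wr(reads$r2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ into named sequence vectors
#' @param r1_path,r2_path FASTQ paths.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  rd <- function(path) {
    ds <- Biostrings::readDNAStringSet(path, format = "fastq")
    stats::setNames(as.character(ds), sub("\\s.*$", "", names(ds)))
  }
  list(r1 = rd(r1_path), r2 = rd(r2_path))
}
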