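#' Call fusion junctions from paired amplicon reads
#'
#' The top-level caller: builds (or reuses) a seed index over the subtelomere
#' panel and toy genome, resolves each read pair into a junction call, and
#' returns one row per read pair together with a failure log. Read 1 is
#' attempted first; if it does not yield two arms, the reverse complement of
#' read 2 is tried. Arm A is the panel arm read in telomere-to-centromere
#' orientation (forward on the panel reference); for genomic fusions arm A is
#' the panel arm and arm B the genomic locus.
#'
#' @param reads An `amplicon_reads` object, a list with named character
#'   vectors `r1`/`r2`, or a length-2 character vector of FASTQ paths.
#' @param panel A `ReferencePanel`.
#' @param genome Optional `SimGenome` enabling genomic-class calls.
#' @param k Seed length.
#' @param min_arm Minimum matched bases per arm.
#' @param max_mh Maximum junction microhomology accepted.
#' @param template_window Window (bp) for the locally-templated insertion test.
#' @param stride Seed sampling stride along reads.
#' @param index Optional prebuilt [index_panel()] result (must match `k`).
#' @return A `junction_calls` data.frame (one row per resolved read pair,
#'   0-based half-open arm coordinates) with a `failures` attribute logging
#'   unresolved reads and reasons.
#' @export
call_junctions <- function(reads, panel, genome = NULL, k = 15L,
                           min_arm = 30L, max_mh = 25L,
                           template_window = 50L, stride = 3L,
                           index = NULL) {
  if (is.character(reads) && length(reads) == 2L)
    reads <- read_fastq_pair(reads[1L], reads[2L])
  stopifnot(!is.null(reads$r1), !is.null(reads$r2))
  if (is.null(index)) index <- index_panel(panel, genome, k = k)
  ids <- names(reads$r1)
  r2rc <- vapply(reads$r2, revcomp, character(1))
  ent <- panel$entries

  rows <- vector("list", length(ids))
  fails <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    res <- NULL
    reason <- NULL
    for (seqs in list(reads$r1[[i]], r2rc[[i]])) {
      al <- align_arms(seqs, index, min_arm = min_arm, max_mh = max_mh,
                       stride = stride)
      if (al$status != "ok") { reason <- al$status; next }
      rj <- resolve_junction(al$left, al$right, seqs, index,
                             max_mh = max_mh, template_window = template_window)
      if (rj$status != "ok") { reason <- rj$status; next }
      res <- list(al = al, rj = rj)
      break
    }
    if (is.null(res)) {
      fails[[length(fails) + 1L]] <- data.frame(read_id = id, reason = reason)
      next
    }
    al <- res$al; rj <- res$rj
    arm_a <- al$left; arm_b <- al$right
    bp_a <- rj$bp_a; bp_b <- rj$bp_b
    iv_a <- rj$ref_iv_a; iv_b <- rj$ref_iv_b
    # arm A must be the panel arm; swap if only the right arm is on the panel
    if (!arm_a$is_panel && arm_b$is_panel) {
      tmp <- arm_a; arm_a <- arm_b; arm_b <- tmp
      tmp <- bp_a; bp_a <- bp_b; bp_b <- tmp
      tmp <- iv_a; iv_a <- iv_b; iv_b <- tmp
    }
    cls <- classify_fusion(arm_a$ref, arm_b$ref, panel)
    rows[[i]] <- data.frame(
      read_id = id, fusion_class = cls,
      ref_a = arm_a$ref, strand_a = arm_a$strand,
      ref_a_start = iv_a[1L], ref_a_end = iv_a[2L], bp_a = bp_a,
      ref_b = arm_b$ref, strand_b = arm_b$strand,
      ref_b_start = iv_b[1L], ref_b_end = iv_b[2L], bp_b = bp_b,
      mh_len = rj$mh_len, ins_seq = rj$ins_seq,
      ins_templated = rj$ins_templated, blunt = rj$blunt,
      score_a = arm_a$score, score_b = arm_b$score,
      family_ambiguous = al$family_ambiguous,
      stringsAsFactors = FALSE)
  }
  calls <- if (any(!vapply(rows, is.null, logical(1))))
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  else
    data.frame(read_id = character(0), fusion_class = character(0))
  if (nrow(calls)) calls <- chromatid_deletions(calls, panel)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(read_id = character(0), reason = character(0))
  class(calls) <- c("junction_calls", "data.frame")
  attr(calls, "failures") <- failures
  calls
}

#' @export
print.junction_calls <- function(x, ...) {
  nf <- nrow(attr(x, "failures") %||% data.frame())
  cat("junction_calls:", nrow(x), "resolved read pairs,", nf, "failures\n")
  if (nrow(x)) {
    print(table(class = x$fusion_class))
    chem <- ifelse(x$mh_len > 0, "MH", ifelse(nzchar(x$ins_seq), "INS", "blunt"))
    print(table(chemistry = chem))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
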