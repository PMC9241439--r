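# Junction resolution: microhomology / insertion / blunt chemistry,
# fusion classification, local-template testing and chromatid deletions.

# oriented 1-based inclusive interval -> original 0-based half-open
to_original_interval <- function(s, e, strand, ref_len) {
  if (strand == "+") c(s - 1L, e) else c(ref_len - e, ref_len - s + 1L)
}

# oriented 0-based cut coordinate -> original 0-based cut coordinate
to_original_cut <- function(cut, strand, ref_len) {
  if (strand == "+") cut else ref_len - cut
}

deletion_from_origin <- function(bp, origin, side) {
  d <- if (side == "right") origin - bp else bp - origin
  if (d < 0)
    stop("data error: breakpoint ", bp,
         " lies on the telomeric side of telomere_origin ", origin)
  d / 1000
}

#' Test whether an insertion is locally templated
#'
#' An insertion is locally templated when it occurs exactly, on either
#' strand, within the supplied reference windows flanking either breakpoint.
#'
#' @param ins_seq Insertion sequence (possibly empty).
#' @param flank_a,flank_b Reference windows around breakpoints A and B
#'   (`template_window` bases each side of the breakpoint).
#' @return `TRUE`, `FALSE`, or `NA` when `ins_seq` is empty (not applicable).
#' @export
detect_local_template <- function(ins_seq, flank_a, flank_b) {
  if (is.na(ins_seq) || !nzchar(ins_seq)) return(NA)
  rc <- revcomp(ins_seq)
  any(vapply(c(flank_a, flank_b), function(w)
    grepl(ins_seq, w, fixed = TRUE) || grepl(rc, w, fixed = TRUE),
    logical(1)))
}

#' Resolve the junction between two aligned arms
#'
#' Computes the junction chemistry from the overlap of the two arms' maximal
#' exact matches on the read: the overlap is the microhomology (bases that
#' extend both arms' reference matches), a gap between the arms is an
#' insertion, and abutting arms are blunt. Exactly one of the three holds for
#' a resolved call. The breakpoint is reported at the leftmost placement
#' consistent with the microhomology: the shared bases are assigned to the
#' second (right) arm.
#'
#' @param left,right Arm records from [align_arms()], ordered by read position.
#' @param read The read sequence the arms came from.
#' @param index The `SeedIndex` used for alignment (provides the references).
#' @param max_mh Maximum credible microhomology; larger overlaps yield an
#'   unresolved call with reason `max_mh_exceeded`.
#' @param template_window Window (bp) on each side of each breakpoint used to
#'   test insertion templating.
#' @return A list with junction chemistry (`mh_len`, `ins_seq`,
#'   `ins_templated`, `blunt`), original-coordinate breakpoints (`bp_a`,
#'   `bp_b`, 0-based), arm reference intervals, and `status`.
#' @export
resolve_junction <- function(left, right, read, index,
                             max_mh = 25L, template_window = 50L) {
  store <- index$store
  ov <- interval_overlap(left, right)
  if (ov > max_mh)
    return(list(status = "max_mh_exceeded"))
  mh <- ov
  ins <- ""
  if (right$read_start - left$read_end >= 2L)
    ins <- substr(read, left$read_end + 1L, right$read_start - 1L)
  blunt <- mh == 0L && !nzchar(ins)

  llen <- store$len[left$ref_id]; rlen <- store$len[right$ref_id]
  # oriented cut coordinates under the leftmost convention
  cut_l <- (left$read_end + left$diag) - mh
  cut_r <- right$read_start + right$diag - 1L
  bp_a <- to_original_cut(cut_l, left$strand, llen)
  bp_b <- to_original_cut(cut_r, right$strand, rlen)

  templated <- NA
  if (nzchar(ins)) {
    fl <- boundary_window(oriented_string(store, left$ref_id, left$strand),
                          cut_l, template_window)
    fr <- boundary_window(oriented_string(store, right$ref_id, right$strand),
                          cut_r, template_window)
    templated <- detect_local_template(ins, fl, fr)
  }
  iv_l <- to_original_interval(left$read_start + left$diag,
                               left$read_end + left$diag, left$strand, llen)
  iv_r <- to_original_interval(right$read_start + right$diag,
                               right$read_end + right$diag, right$strand, rlen)
  list(status = "ok", mh_len = mh, ins_seq = ins, ins_templated = templated,
       blunt = blunt, bp_a = bp_a, bp_b = bp_b,
       ref_iv_a = iv_l, ref_iv_b = iv_r)
}

#' Classify a fusion from its two arm references
#'
#' Intra-chromosomal: both arms on the same panel member, or on members of
#' the same family (family-level ambiguity is flagged upstream, never
#' silently resolved — homology within a family precludes definitive
#' discrimination of true sister-chromatid fusions). Inter-chromosomal: both
#' arms on the panel but in different families. Genomic: exactly one arm on
#' the panel. Neither arm on the panel is not a telomere fusion.
#'
#' @param ref_a,ref_b Reference names of the two arms.
#' @param panel The `ReferencePanel`.
#' @return One of `"intra"`, `"inter"`, `"genomic"`, `"unresolved"`.
#' @export
classify_fusion <- function(ref_a, ref_b, panel) {
  ent <- panel$entries
  pa <- ref_a %in% ent$name; pb <- ref_b %in% ent$name
  if (pa && pb) {
    if (ref_a == ref_b) return("intra")
    fa <- ent$family[ent$name == ref_a]; fb <- ent$family[ent$name == ref_b]
    if (fa == fb) "intra" else "inter"
  } else if (pa || pb) "genomic" else "unresolved"
}

#' Per-chromatid deletions and their asymmetry for junction calls
#'
#' Deletion is the distance, in kb, from a panel entry's telomere origin to
#' the arm breakpoint, measured toward the centromere-proximal side. It is
#' undefined (NA) for a genomic arm, and the asymmetry is the absolute
#' difference when both are defined.
#'
#' @param calls A `junction_calls` data.frame (or any frame with `ref_a`,
#'   `ref_b`, `bp_a`, `bp_b`).
#' @param panel The `ReferencePanel` giving telomere origins.
#' @return The calls with `deletion_a_kb`, `deletion_b_kb`, `asymmetry_kb`
#'   (re)computed.
#' @export
chromatid_deletions <- function(calls, panel) {
  ent <- panel$entries
  one <- function(ref, bp) {
    i <- match(ref, ent$name)
    if (is.na(i) || is.na(bp)) return(NA_real_)
    deletion_from_origin(bp, ent$telomere_origin[i], ent$telomere_side[i])
  }
  calls$deletion_a_kb <- mapply(one, calls$ref_a, calls$bp_a)
  calls$deletion_b_kb <- mapply(one, calls$ref_b, calls$bp_b)
  calls$asymmetry_kb <- abs(calls$deletion_a_kb - calls$deletion_b_kb)
  calls
}
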