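# Arm alignment: seeded, ungapped, exact-run extension.
#
# A candidate arm is a maximal run of exactly matching bases on one diagonal
# of (reference, strand), grown outward from a seed k-mer hit. Exact runs
# make junction placement deterministic and identical to a brute-force scan:
# a run ends precisely at the first mismatching base, so the overlap of the
# two chosen arms on the read *is* the junction microhomology.

# extend an exact match run outward from [rs, re] (read coords, all matching)
extend_exact <- function(readc, refc, diag, rs, re) {
  n_read <- length(readc); n_ref <- length(refc)
  i <- re
  while (i < n_read && i + diag < n_ref && readc[i + 1L] != "N" &&
         readc[i + 1L] == refc[i + 1L + diag]) i <- i + 1L
  j <- rs
  while (j > 1L && j - 1L + diag >= 1L && readc[j - 1L] != "N" &&
         readc[j - 1L] == refc[j - 1L + diag]) j <- j - 1L
  c(j, i)
}

# all candidate arms for one read against the index
candidate_arms <- function(read, index, stride = 3L) {
  k <- index$k
  n <- nchar(read)
  if (n == 0L) stop("input error: empty read")
  starts <- kmer_starts(n, k, stride)
  if (!length(starts)) return(NULL)
  kms <- substring(read, starts, starts + k - 1L)
  keep <- !grepl("N", kms, fixed = TRUE)
  kms <- kms[keep]; starts <- starts[keep]
  if (!length(kms)) return(NULL)
  hits <- mget(kms, envir = index$env, ifnotfound = list(NULL))
  nh <- lengths(hits)
  if (sum(nh) == 0L) return(NULL)
  ids <- unlist(hits, use.names = FALSE)
  rp <- rep.int(starts, nh)
  ref_id <- index$ref_id[ids]; pos <- index$pos[ids]; strand <- index$strand[ids]
  diag <- pos - rp
  key <- paste(ref_id, strand, diag, sep = ":")
  readc <- seq_chars(read)
  out <- list()
  for (grp in split(seq_along(key), key)) {
    ri <- ref_id[grp[1L]]; st <- strand[grp[1L]]; dg <- diag[grp[1L]]
    refc <- oriented_chars(index$store, ri, c("+", "-")[st])
    seed_rp <- sort(unique(rp[grp]))
    done_to <- 0L
    for (srp in seed_rp) {
      if (srp <= done_to) next
      run <- extend_exact(readc, refc, dg, srp, srp + k - 1L)
      done_to <- run[2L]
      out[[length(out) + 1L]] <- list(
        ref_id = ri, ref = index$store$names[ri], strand = c("+", "-")[st],
        diag = dg, read_start = run[1L], read_end = run[2L],
        score = run[2L] - run[1L] + 1L,
        is_panel = index$store$is_panel[ri],
        family = index$store$family[ri])
    }
  }
  out
}

interval_overlap <- function(a, b) {
  max(0L, min(a$read_end, b$read_end) - max(a$read_start, b$read_start) + 1L)
}

# deterministic preference among equal-score candidates:
# panel before genome, then reference name, then forward strand
tie_rank <- function(cands) {
  order(-vapply(cands, `[[`, integer(1), "score"),
        !vapply(cands, `[[`, logical(1), "is_panel"),
        vapply(cands, `[[`, character(1), "ref"),
        vapply(cands, `[[`, character(1), "strand"))
}

#' Align the two arms of a putative fusion read
#'
#' Finds the pair of non-redundant exact-match arms maximizing matched bases:
#' the best candidate overall, plus the best candidate overlapping it on the
#' read by at most `max_mh` bases while contributing at least `min_arm` new
#' bases. Equal-score alternatives from the same chromosome-end family are
#' recorded as a family ambiguity (and never silently resolved); equal-score
#' alternatives from unrelated references make the read ambiguous.
#'
#' @param read Character scalar over ACGTN.
#' @param index A `SeedIndex` from [index_panel()].
#' @param min_arm Minimum matched bases per arm.
#' @param max_mh Maximum junction overlap (microhomology ceiling).
#' @param stride Seed sampling stride along the read.
#' @return A list: `status` (`"ok"` or a failure reason among `no-seed`,
#'   `single-arm`, `ambiguous`), `left`/`right` arm records ordered by read
#'   position, and `family_ambiguous`.
#' @export
align_arms <- function(read, index, min_arm = 30L, max_mh = 25L, stride = 3L) {
  stopifnot(inherits(index, "SeedIndex"))
  if (!nzchar(read)) stop("input error: empty read")
  if (grepl("[^ACGTN]", read)) stop("input error: read contains non-ACGTN characters")
  cands <- candidate_arms(read, index, stride)
  if (is.null(cands) || !length(cands))
    return(list(status = "no-seed", left = NULL, right = NULL,
                family_ambiguous = FALSE))
  ord <- tie_rank(cands)
  cands <- cands[ord]
  a1 <- cands[[1L]]
  if (a1$score < min_arm)
    return(list(status = "no-seed", left = NULL, right = NULL,
                family_ambiguous = FALSE))
  # family ambiguity: a same-family alternative within `fam_margin` matched
  # bases of the chosen arm cannot be discriminated reliably — a single
  # divergent site may be defeated by chance junction-side extension, so
  # near-ties are flagged, never silently resolved
  fam_margin <- 4L
  same_span <- function(x, y) x$read_start == y$read_start && x$read_end == y$read_end
  is_fam_alt <- function(cc, a) {
    cc$ref != a$ref && !is.na(cc$family) && !is.na(a$family) &&
      cc$family == a$family && interval_overlap(cc, a) >= a$score / 2 &&
      cc$score >= a$score - fam_margin
  }
  fam_amb <- FALSE
  for (cc in cands[-1L]) {
    if (is_fam_alt(cc, a1)) fam_amb <- TRUE
    else if (cc$score == a1$score && cc$ref != a1$ref && same_span(cc, a1))
      return(list(status = "ambiguous", left = NULL, right = NULL,
                  family_ambiguous = FALSE))
  }
  a2 <- NULL
  for (cc in cands[-1L]) {
    ov <- interval_overlap(cc, a1)
    if (ov > max_mh) next
    if (cc$score - ov < min_arm) next
    a2 <- cc
    break
  }
  if (is.null(a2))
    return(list(status = "single-arm", left = NULL, right = NULL,
                family_ambiguous = fam_amb))
  for (cc in cands) {
    if (identical(cc, a2) || identical(cc, a1)) next
    if (is_fam_alt(cc, a2)) fam_amb <- TRUE
  }
  arms <- if (a1$read_start <= a2$read_start) list(a1, a2) else list(a2, a1)
  list(status = "ok", left = arms[[1L]], right = arms[[2L]],
       family_ambiguous = fam_amb)
}
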