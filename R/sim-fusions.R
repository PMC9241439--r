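#' Configuration for simulating ground-truth telomere fusion events
#'
#' Controls the class mixture (intra-chromosomal sister-chromatid fusions,
#' inter-chromosomal fusions between different chromosome-end families, and
#' genomic fusions between a telomere and a distant locus), the junction
#' chemistry mixture (microhomology / insertion / blunt), and the chromatid
#' deletion size distribution. An event has exactly one chemistry: MH > 0,
#' a non-empty insertion, or a blunt junction.
#'
#' Junction chemistry is realized against the fixed panel/genome sequences:
#' partner breakpoints are chosen so that the sequence-determined
#' microhomology at the junction equals the requested length (rejection over
#' candidate positions). Insertions are rejected until their ends cannot
#' extend either arm, so the simulator's truth table is exact under the same
#' junction definitions the caller uses.
#'
#' @param n_events Number of fusion events.
#' @param class_mixture Named proportions over intra/inter/genomic, sum 1.
#' @param mh_length_distribution [fuseq_dist] over positive integers (bp).
#' @param ins_fraction Proportion of events with an insertion.
#' @param ins_templated_fraction Among insertion events, proportion copied
#'   from within `template_window_bp` of either breakpoint (either strand).
#' @param ins_length_distribution [fuseq_dist] over positive integers (bp).
#'   The default support of 6-12 bp keeps the occurrence-based "locally
#'   templated" call specific: a random insertion much shorter than 6 bp is
#'   found by chance in almost any 100-bp template window, which would make
#'   untemplated truth unrealizable.
#' @param blunt_fraction Proportion of blunt events; the MH proportion is
#'   `1 - ins_fraction - blunt_fraction`.
#' @param deletion_kb_distribution [fuseq_dist] over non-negative reals (kb),
#'   governing erosion of each chromatid from its telomere origin.
#' @param template_window_bp Window on each side of each breakpoint defining
#'   "locally templated".
#' @param seed Non-negative integer seed.
#' @export
fusion_sim_config <- function(n_events = 500L,
                              class_mixture = c(intra = 0.40, inter = 0.25,
                                                genomic = 0.35),
                              mh_length_distribution = dist_mh_geometric(4),
                              ins_fraction = 0.10,
                              ins_templated_fraction = 0.70,
                              ins_length_distribution = dist_discrete(6:12),
                              blunt_fraction = 0.25,
                              deletion_kb_distribution = dist_gamma_trunc(2, 1, 4.5),
                              template_window_bp = 50L,
                              seed = 1L) {
  if (n_events < 1) stop("configuration error: n_events must be positive")
  if (!setequal(names(class_mixture), c("intra", "inter", "genomic")))
    stop("configuration error: class_mixture must name intra, inter, genomic")
  if (abs(sum(class_mixture) - 1) > 1e-9)
    stop("configuration error: class_mixture must sum to 1")
  if (any(class_mixture < 0)) stop("configuration error: negative mixture proportion")
  if (ins_fraction < 0 || blunt_fraction < 0 || ins_fraction + blunt_fraction > 1)
    stop("configuration error: ins_fraction + blunt_fraction must lie in [0,1]")
  if (ins_templated_fraction < 0 || ins_templated_fraction > 1)
    stop("configuration error: ins_templated_fraction outside [0,1]")
  stopifnot(inherits(mh_length_distribution, "fuseq_dist"),
            inherits(ins_length_distribution, "fuseq_dist"),
            inherits(deletion_kb_distribution, "fuseq_dist"))
  structure(list(n_events = as.integer(n_events),
                 class_mixture = class_mixture[c("intra", "inter", "genomic")],
                 mh_length_distribution = mh_length_distribution,
                 ins_fraction = ins_fraction,
                 ins_templated_fraction = ins_templated_fraction,
                 ins_length_distribution = ins_length_distribution,
                 blunt_fraction = blunt_fraction,
                 deletion_kb_distribution = deletion_kb_distribution,
                 template_window_bp = as.integer(template_window_bp),
                 seed = as.integer(seed)),
            class = "fusion_sim_config")
}

# backward/forward exact-match run lengths at candidate junctions.
# fa_c: arm-A reference as a character vector (read orientation), p the
# 0-based boundary (A keeps fa_c[1..p]); fb_c likewise with candidate
# boundaries `xs` (B keeps fb_c[(x+1)..]). Runs are capped at `cap`.
junction_runs <- function(fa_c, p, fb_c, xs, cap) {
  nb <- length(fb_c); na <- length(fa_c)
  b <- integer(length(xs)); f <- integer(length(xs))
  alive <- rep(TRUE, length(xs))
  for (j in seq_len(cap)) {
    ia <- p + 1L - j
    ib <- xs + 1L - j
    eq <- if (ia < 1L) rep(FALSE, length(xs)) else {
      ok <- ib >= 1L
      e <- rep(FALSE, length(xs)); e[ok] <- fb_c[ib[ok]] == fa_c[ia]
      e
    }
    b <- b + as.integer(alive & eq); alive <- alive & eq
  }
  alive <- rep(TRUE, length(xs))
  for (j in seq_len(cap)) {
    ia <- p + j
    ib <- xs + j
    eq <- if (ia > na) rep(FALSE, length(xs)) else {
      ok <- ib <= nb
      e <- rep(FALSE, length(xs)); e[ok] <- fb_c[ib[ok]] == fa_c[ia]
      e
    }
    f <- f + as.integer(alive & eq); alive <- alive & eq
  }
  list(b = b, f = f)
}

# oriented window around a 0-based boundary `bp` on oriented sequence `s`
boundary_window <- function(s, bp, w) {
  substr(s, max(1L, bp - w + 1L), min(nchar(s), bp + w))
}

ins_occurs <- function(ins, windows) {
  any(vapply(windows, function(w)
    grepl(ins, w, fixed = TRUE) || grepl(revcomp(ins), w, fixed = TRUE),
    logical(1)))
}

#' Simulate ground-truth telomere fusion events
#'
#' Draws fusion events against a subtelomere panel (and toy genome for the
#' genomic class) and returns an exact truth table. Breakpoints and deletions
#' are recorded under the leftmost junction-placement convention: when a
#' junction has microhomology, the shared bases are assigned to the
#' centromere-distal (second) arm, matching the caller's reporting
#' convention, so exact recovery is well defined.
#'
#' @param panel A `ReferencePanel` from [build_subtelomere_panel()].
#' @param genome A `SimGenome`, required when `class_mixture["genomic"] > 0`.
#' @param config A [fusion_sim_config()].
#' @return A data.frame of class `fusion_truth`, one row per event, with the
#'   fusion class, arm references/strands, 0-based breakpoints, mh_len,
#'   ins_seq, ins_templated, per-chromatid deletions in kb, plus internal
#'   rendering coordinates (columns prefixed with a dot).
#' @export
simulate_fusion_events <- function(panel, genome = NULL,
                                   config = fusion_sim_config()) {
  stopifnot(inherits(panel, "ReferencePanel"))
  if (!inherits(config, "fusion_sim_config"))
    stop("configuration error: expected a fusion_sim_config object")
  if (config$class_mixture[["genomic"]] > 0 && is.null(genome))
    stop("configuration error: genomic events requested but no genome supplied")
  if (config$class_mixture[["inter"]] > 0 &&
      length(unique(panel$entries$family)) < 2)
    stop("configuration error: inter events need at least two families")
  if (nrow(panel$entries) == 0) stop("panel is empty")

  with_stream_seed(config$seed, "fusions", {
    n <- config$n_events
    mix <- config$class_mixture
    classes <- sample(names(mix), n, replace = TRUE, prob = mix)
    chem_p <- c(MH = 1 - config$ins_fraction - config$blunt_fraction,
                INS = config$ins_fraction, blunt = config$blunt_fraction)
    chems <- sample(names(chem_p), n, replace = TRUE, prob = chem_p)
    mh_targets <- ifelse(chems == "MH", rdist(config$mh_length_distribution, n), 0L)

    ent <- panel$entries
    # read-oriented sequence cache: panel arm A is forward; the partner
    # telomere arrives reverse-complemented (head-to-head geometry)
    rev_str <- vapply(panel$seq, revcomp, character(1))
    fwd <- lapply(panel$seq, seq_chars)
    rev_panel <- lapply(rev_str, seq_chars)
    if (!is.null(genome)) {
      grev_str <- vapply(genome$seq, revcomp, character(1))
      gchars <- list(fwd = lapply(genome$seq, seq_chars),
                     rev = lapply(grev_str, seq_chars))
    }
    w <- config$template_window_bp
    min_keep <- 320L  # retained bp needed for amplicon flank + read placement

    draw_bp <- function(origin) {
      repeat {
        p <- origin - as.integer(round(rdist(config$deletion_kb_distribution, 1) * 1000))
        if (p >= min_keep && p <= origin) return(p)
      }
    }

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- classes[i]; chem <- chems[i]; m <- as.integer(mh_targets[i])
      if (cls == "intra") {
        a <- sample(ent$name, 1L)
        b_ref <- a; b_strand <- "-"
      } else if (cls == "inter") {
        a <- sample(ent$name, 1L)
        other <- ent$name[ent$family != ent$family[ent$name == a]]
        b_ref <- if (length(other) == 1L) other else sample(other, 1L)
        b_strand <- "-"
      } else {
        a <- sample(ent$name, 1L)
        b_ref <- sample(names(genome$chrom_lengths), 1L,
                        prob = genome$chrom_lengths)
        b_strand <- sample(c("+", "-"), 1L)
      }
      origin_a <- ent$telomere_origin[ent$name == a]
      fa_c <- fwd[[a]]
      fa_str <- panel$seq[[a]]
      # insertion attributes are fixed per event before any rejection, so
      # differential rejection rates cannot skew the templated fraction
      if (chem == "INS") {
        ell <- as.integer(rdist(config$ins_length_distribution, 1))
        templated <- stats::runif(1) < config$ins_templated_fraction
      }

      done <- FALSE; tries_p <- 0L
      while (!done) {
        tries_p <- tries_p + 1L
        if (tries_p > 5000L)
          stop("could not realize junction chemistry for event ", i)
        p <- draw_bp(origin_a)
        if (cls == "genomic") {
          lenb <- genome$chrom_lengths[[b_ref]]
          fb_c <- if (b_strand == "+") gchars$fwd[[b_ref]] else gchars$rev[[b_ref]]
          fb_str <- if (b_strand == "+") genome$seq[[b_ref]] else grev_str[[b_ref]]
          x_lo <- min_keep; x_hi <- lenb - min_keep
          x0 <- sample.int(x_hi - x_lo + 1L, 1L) + x_lo - 1L
        } else {
          lenb <- ent$length[ent$name == b_ref]
          origin_b <- ent$telomere_origin[ent$name == b_ref]
          fb_c <- rev_panel[[b_ref]]
          fb_str <- rev_str[[b_ref]]
          # oriented boundary x corresponds to retained length q = lenb - x;
          # the extra margin keeps bp_b = q + mh on the subtelomeric side of
          # the telomere origin
          x_lo <- lenb - origin_b + 16L; x_hi <- lenb - min_keep
          x0 <- min(x_hi, max(x_lo, lenb - draw_bp(origin_b)))
        }
        if (x_hi <= x_lo) stop("reference too short for simulation settings")

        if (chem == "INS") {
          x <- x0
          wa <- boundary_window(fa_str, p, w)
          wbs <- boundary_window(fb_str, x, w)
          ok_ins <- FALSE
          for (try_i in 1:200) {
            if (templated) {
              src <- if (stats::runif(1) < 0.5) wa else wbs
              if (nchar(src) < ell) next
              pos <- sample.int(nchar(src) - ell + 1L, 1L)
              ins <- substr(src, pos, pos + ell - 1L)
              if (stats::runif(1) < 0.5) ins <- revcomp(ins)
            } else {
              ins <- random_dna(ell)
            }
            ic <- seq_chars(ins)
            # insertion ends must not extend either arm's reference match
            if (p + 1L <= length(fa_c) && ic[1] == fa_c[p + 1L]) next
            if (x >= 1L && ic[ell] == fb_c[x]) next
            if (!templated && ins_occurs(ins, list(wa, wbs))) next
            ok_ins <- TRUE
            break
          }
          if (!ok_ins) next
          s_back <- 0L; f_fwd <- 0L
          done <- TRUE
        } else {
          # scan a window of candidate partner boundaries for realized MH == m;
          # long microhomologies need the full range (they are rare on fixed
          # random sequence), which mildly loosens the arm-B deletion draw
          span <- if (m <= 4L) 300L else (x_hi - x_lo)
          xs <- max(x_lo, x0 - span):min(x_hi, x0 + span)
          jr <- junction_runs(fa_c, p, fb_c, xs, cap = m + 1L)
          valid <- which(jr$b + jr$f == m)
          if (!length(valid)) next
          pick <- valid[sample.int(length(valid), 1L)]
          x <- xs[pick]; s_back <- jr$b[pick]; f_fwd <- jr$f[pick]
          ins <- ""; templated <- NA
          done <- TRUE
        }
      }

      bp_a <- p - s_back  # leftmost convention: MH assigned to arm B
      if (cls == "genomic") {
        bp_b <- if (b_strand == "+") x - s_back else lenb - (x - s_back)
        del_b <- NA_real_
      } else {
        q <- lenb - x
        bp_b <- q + s_back
        del_b <- (origin_b - bp_b) / 1000
      }
      rows[[i]] <- data.frame(
        event_id = sprintf("ev%05d", i),
        fusion_class = cls, chemistry = chem,
        ref_a = a, strand_a = "+", bp_a = bp_a,
        ref_b = b_ref, strand_b = b_strand, bp_b = bp_b,
        mh_len = if (chem == "MH") m else 0L,
        ins_seq = ins, ins_templated = templated,
        deletion_a_kb = (origin_a - bp_a) / 1000,
        deletion_b_kb = del_b,
        .p = p, .x = x, .s = s_back, .f = f_fwd,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("fusion_truth", "data.frame")
    out
  })
}
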