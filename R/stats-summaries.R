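#' Telomere fusion frequency per diploid genome
#'
#' Frequency is the number of non-constitutive fusion amplicons relative to
#' the DNA input, expressed per diploid genome:
#' `count / (dna_input_ng * 1000 / pg_per_diploid_genome)`. The default mass
#' of one diploid human genome is 6.6 pg.
#'
#' @param amplicon_count Non-negative integer count of fusion amplicons.
#' @param dna_input_ng DNA input in ng (positive).
#' @param pg_per_diploid_genome Mass of one diploid genome in pg.
#' @param sample_id Optional sample label.
#' @return A one-row `FusionFrequency` data.frame.
#' @examples
#' fusion_frequency(5, 66)  # 66 ng = 10,000 diploid genomes -> 5e-4
#' @export
fusion_frequency <- function(amplicon_count, dna_input_ng,
                             pg_per_diploid_genome = 6.6,
                             sample_id = NA_character_) {
  if (any(dna_input_ng <= 0)) stop("input error: DNA input must be positive")
  if (any(amplicon_count < 0)) stop("input error: negative amplicon count")
  if (any(pg_per_diploid_genome <= 0)) stop("input error: non-positive genome mass")
  genomes <- dna_input_ng * 1000 / pg_per_diploid_genome
  data.frame(sample_id = sample_id,
             amplicon_count = amplicon_count,
             dna_input_ng = dna_input_ng,
             pg_per_diploid_genome = pg_per_diploid_genome,
             frequency_per_diploid_genome = amplicon_count / genomes)
}

#' Maximal fusion frequency over a sampled time course
#'
#' @param counts,inputs_ng Vectors over time points.
#' @param pg_per_diploid_genome Mass of one diploid genome in pg.
#' @export
max_fusion_frequency <- function(counts, inputs_ng, pg_per_diploid_genome = 6.6) {
  ff <- fusion_frequency(counts, inputs_ng, pg_per_diploid_genome)
  max(ff$frequency_per_diploid_genome)
}

call_chemistry <- function(calls) {
  ifelse(calls$mh_len > 0, "MH",
         ifelse(nzchar(calls$ins_seq) & !is.na(calls$ins_seq), "INS", "blunt"))
}

#' Fusion class proportions
#'
#' Proportions of resolved calls classified as genomic, inter-chromosomal or
#' intra-chromosomal, with counts alongside.
#'
#' @param calls A `junction_calls` data.frame.
#' @return Data.frame with class, count, proportion (sums to 1).
#' @export
class_proportions <- function(calls) {
  ok <- calls$fusion_class %in% c("intra", "inter", "genomic")
  if (!any(ok)) stop("input error: no resolved calls")
  tb <- table(factor(calls$fusion_class[ok], c("genomic", "inter", "intra")))
  data.frame(fusion_class = names(tb), count = as.integer(tb),
             proportion = as.numeric(tb) / sum(tb))
}

t_ci <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 2) return(c(NA_real_, NA_real_))
  se <- stats::sd(x) / sqrt(n)
  mean(x) + c(-1, 1) * stats::qt(1 - (1 - level) / 2, n - 1) * se
}

#' Summarize junction chemistry per fusion class
#'
#' For each fusion class: proportions of microhomology / insertion / blunt
#' junctions (summing to 1), the mean microhomology and insertion lengths
#' with t-based 95% confidence intervals, and the locally-templated fraction
#' among insertions. Classes with no calls are omitted with a warning, never
#' fabricated.
#'
#' @param calls A `junction_calls` data.frame.
#' @param by_class Summarize per fusion class (default) or pooled.
#' @return A `JunctionSummary` data.frame, one row per class.
#' @export
summarize_junctions <- function(calls, by_class = TRUE) {
  ok <- calls[calls$fusion_class %in% c("intra", "inter", "genomic"), ,
              drop = FALSE]
  if (!nrow(ok)) stop("input error: no resolved calls")
  groups <- if (by_class) split(ok, factor(ok$fusion_class,
                                           c("genomic", "inter", "intra")))
            else list(all = ok)
  empty <- names(groups)[vapply(groups, nrow, integer(1)) == 0]
  if (length(empty))
    warning("no calls in class(es): ", paste(empty, collapse = ", "))
  groups <- groups[vapply(groups, nrow, integer(1)) > 0]
  out <- lapply(names(groups), function(g) {
    cc <- groups[[g]]
    chem <- call_chemistry(cc)
    n <- nrow(cc)
    mh <- cc$mh_len[chem == "MH"]
    il <- nchar(cc$ins_seq[chem == "INS"])
    tmpl <- cc$ins_templated[chem == "INS"]
    ci_mh <- t_ci(mh); ci_ins <- t_ci(il)
    data.frame(group = g, n = n,
               prop_mh = mean(chem == "MH"),
               prop_ins = mean(chem == "INS"),
               prop_blunt = mean(chem == "blunt"),
               mean_mh_bp = if (length(mh)) mean(mh) else NA_real_,
               mh_ci_lo = ci_mh[1], mh_ci_hi = ci_mh[2],
               mean_ins_bp = if (length(il)) mean(il) else NA_real_,
               ins_ci_lo = ci_ins[1], ins_ci_hi = ci_ins[2],
               templated_fraction = if (length(tmpl)) mean(tmpl, na.rm = TRUE)
                                    else NA_real_)
  })
  do.call(rbind, out)
}

#' Growth divergence from population-doubling time series
#'
#' Fits an ordinary least-squares line to each record's population doublings
#' over time and reports the slope; the divergence of a clone from its
#' control is the control slope minus the clone slope (PD/day lost).
#'
#' @param clone,control Data.frames with columns `time_days` and
#'   `population_doublings` (at least 3 points each).
#' @return List with `clone_slope`, `control_slope`, `divergence`.
#' @export
growth_divergence <- function(clone, control) {
  slope <- function(d) {
    stopifnot(all(c("time_days", "population_doublings") %in% names(d)))
    if (nrow(d) < 3) stop("input error: need at least 3 time points")
    if (stats::var(d$time_days) == 0) stop("input error: degenerate time vector")
    unname(stats::coef(stats::lm(population_doublings ~ time_days, data = d))[2])
  }
  cs <- slope(clone); ks <- slope(control)
  list(clone_slope = cs, control_slope = ks, divergence = ks - cs)
}

#' Welch's unequal-variance t-test comparing groups of growth divergences
#' @param x,y Numeric vectors of per-clone divergences.
#' @return Two-sided p-value.
#' @export
welch_t_p <- function(x, y) {
  stats::t.test(x, y, var.equal = FALSE)$p.value
}
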