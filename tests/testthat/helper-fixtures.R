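# Shared fixtures, built once per test run and cached. Everything is
# generated in code under fixed seeds; no files ship with the package.

.tf_cache <- new.env(parent = emptyenv())

tf_once <- function(key, expr) {
  if (!exists(key, envir = .tf_cache))
    assign(key, force(expr), envir = .tf_cache)
  get(key, envir = .tf_cache)
}

tf_panel <- function() tf_once("panel", build_subtelomere_panel(sim_panel_config(seed = 101)))
tf_genome <- function() tf_once("genome", simulate_genome(sim_genome_config(seed = 101)))
tf_index <- function() tf_once("index", index_panel(tf_panel(), tf_genome(), k = 15))

# cohort A: 2,000 events at the junction-chemistry study mixture
# (MH 60% mean 4 bp, INS 25% with templated fraction 0.7, blunt 15%;
# class mixture 25/25/50), error-free reads, called end to end
tf_cohortA <- function() tf_once("cohortA", {
  panel <- tf_panel(); genome <- tf_genome()
  cfg <- fusion_sim_config(
    n_events = 2000L,
    class_mixture = c(intra = 0.25, inter = 0.25, genomic = 0.50),
    mh_length_distribution = dist_mh_geometric(4),
    ins_fraction = 0.25, ins_templated_fraction = 0.7,
    blunt_fraction = 0.15, seed = 202)
  truth <- simulate_fusion_events(panel, genome, cfg)
  reads <- render_amplicon_reads(truth, panel, genome, seed = 202)
  calls <- call_junctions(reads, panel, genome, index = tf_index())
  list(cfg = cfg, truth = truth, reads = reads, calls = calls)
})

# cohort B: 500 error-free events per fusion class, for ground-truth recovery
tf_cohortB <- function() tf_once("cohortB", {
  panel <- tf_panel(); genome <- tf_genome()
  cfg <- fusion_sim_config(
    n_events = 1500L,
    class_mixture = c(intra = 1/3, inter = 1/3, genomic = 1/3),
    seed = 303)
  truth <- simulate_fusion_events(panel, genome, cfg)
  reads <- render_amplicon_reads(truth, panel, genome, seed = 303)
  calls <- call_junctions(reads, panel, genome, index = tf_index())
  list(cfg = cfg, truth = truth, reads = reads, calls = calls)
})

# merge calls with the truth table by read -> event
tf_merged <- function(cohort) {
  m <- merge(cohort$reads$reads[c("read_id", "event_id")],
             as.data.frame(cohort$calls), by = "read_id")
  merge(m, as.data.frame(cohort$truth), by = "event_id",
        suffixes = c(".call", ".true"))
}

# exact-recovery indicator: class, mh length, insertion sequence and both
# deletions must match the truth record
tf_recovered <- function(m) {
  delb_ok <- (is.na(m$deletion_b_kb.true) & is.na(m$deletion_b_kb.call)) |
    (!is.na(m$deletion_b_kb.true) & !is.na(m$deletion_b_kb.call) &
       abs(m$deletion_b_kb.call - m$deletion_b_kb.true) < 1e-9)
  m$fusion_class.call == m$fusion_class.true &
    m$mh_len.call == m$mh_len.true &
    m$ins_seq.call == m$ins_seq.true &
    abs(m$deletion_a_kb.call - m$deletion_a_kb.true) < 1e-9 &
    delb_ok
}

# independent brute-force junction microhomology oracle: plain character
# loops over the two oriented reference strings at the called diagonals
tf_mh_oracle <- function(read, left_ref, left_diag, right_ref, right_diag,
                         anchor_left, anchor_right) {
  rc <- strsplit(read, "")[[1]]
  lc <- strsplit(left_ref, "")[[1]]
  rrc <- strsplit(right_ref, "")[[1]]
  i <- anchor_left
  while (i < length(rc) && i + left_diag < length(lc) &&
         rc[i + 1] == lc[i + 1 + left_diag]) i <- i + 1
  j <- anchor_right
  while (j > 1 && j - 1 + right_diag >= 1 && rc[j - 1] == rrc[j - 1 + right_diag])
    j <- j - 1
  max(0L, i - j + 1L)
}

revcomp_test <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# exact binomial 99% CI bounds for an observed proportion check
tf_binom99 <- function(p, n) {
  c(lo = stats::qbinom(0.005, n, p) / n, hi = stats::qbinom(0.995, n, p) / n)
}
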