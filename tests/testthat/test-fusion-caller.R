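# The junction caller: seed index, arm alignment, junction chemistry,
# classification and deletions, checked against constructed sequences and a
# brute-force microhomology oracle.

# a panel object built from explicit sequences, bypassing the generator
manual_panel <- function(seqs, families, origin = 0L, side = "left") {
  entries <- data.frame(name = names(seqs), family = families,
                        length = nchar(unname(unlist(seqs))),
                        telomere_origin = origin, telomere_side = side,
                        stringsAsFactors = FALSE)
  structure(list(entries = entries, seq = unlist(seqs)),
            class = "ReferencePanel")
}

rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

test_that("the seed index retrieves every k-mer at its true offset, keeping repeats", {
  s <- rand_seq(1000, 1)
  pan <- manual_panel(list(ref1 = s), "f1")
  idx <- index_panel(pan, k = 15)
  probe <- c(1L, 250L, 986L)
  for (st in probe) {
    km <- substr(s, st, st + 14L)
    hits <- lookup_kmer(idx, km)
    expect_true(any(hits$ref == "ref1" & hits$pos == st & hits$strand == "+"))
  }
  # a k-mer planted in two references returns both hits
  shared <- substr(s, 101, 115)
  s2 <- paste0(rand_seq(400, 2), shared, rand_seq(400, 3))
  pan2 <- manual_panel(list(ref1 = s, ref2 = s2), c("f1", "f2"))
  idx2 <- index_panel(pan2, k = 15)
  hits <- lookup_kmer(idx2, shared)
  expect_setequal(hits$ref[hits$strand == "+"], c("ref1", "ref2"))

  expect_error(index_panel(pan, k = 51), "configuration error")
  expect_error(index_panel(manual_panel(list(tiny = rand_seq(12, 4)), "f"), k = 15),
               "shortest reference")
})

test_that("two-arm reads resolve at their true offsets; degenerate reads fail with reasons", {
  panel <- tf_panel(); genome <- tf_genome(); idx <- tf_index()
  read <- paste0(substr(panel$seq[["17p"]], 1001, 1070),
                 substr(genome$seq[["chr2"]], 5001, 5070))
  al <- align_arms(read, idx)
  expect_equal(al$status, "ok")
  expect_equal(al$left$ref, "17p")
  expect_equal(al$left$diag, 1000L)   # oriented offset of the 17p arm
  expect_equal(al$right$ref, "chr2")
  expect_equal(al$right$strand, "+")
  expect_equal(al$right$diag + 71L, 5001L)

  one <- align_arms(substr(panel$seq[["XpYp"]], 201, 340), idx)
  expect_equal(one$status, "single-arm")
  expect_equal(align_arms(strrep("N", 120), idx)$status, "no-seed")
  expect_error(align_arms("", idx), "empty read")
  expect_error(align_arms("ACGTQ", idx), "non-ACGTN")
})

test_that("a planted 4 bp microhomology junction is recovered with its brute-force oracle", {
  # flank A ends ...ACGTAC, flank B begins GTACGG; the read runs ...ACGTACGG...
  a_body <- rand_seq(80, 11)
  b_body <- rand_seq(80, 12)
  refA <- paste0(rand_seq(30, 13), a_body, "ACGTAC", "TTCAGTCA", rand_seq(30, 14))
  refB <- paste0(rand_seq(30, 15), "CATG", "GTACGG", b_body, rand_seq(30, 16))
  # neighbours chosen so extension stops exactly at the planted junction:
  # refA continues with T (read continues G), refB is preceded by G (read has C)
  pan <- manual_panel(list(refA = refA, refB = refB), c("fa", "fb"))
  idx <- index_panel(pan, k = 15)
  read <- paste0(a_body, "ACGTAC", "GG", b_body)
  al <- align_arms(read, idx)
  expect_equal(al$status, "ok")
  rj <- resolve_junction(al$left, al$right, read, idx)
  expect_equal(rj$mh_len, 4L)
  expect_equal(rj$ins_seq, "")
  expect_false(rj$blunt)
  oracle <- tf_mh_oracle(read, refA, al$left$diag, refB, al$right$diag,
                         anchor_left = 40L, anchor_right = nchar(read) - 40L)
  expect_equal(rj$mh_len, oracle)
})

test_that("insertions absent from both flanks are reported verbatim with mh = 0", {
  a_body <- rand_seq(90, 21)
  b_body <- rand_seq(90, 22)
  refA <- paste0(a_body, "CCGGA", rand_seq(40, 23))
  refB <- paste0(rand_seq(40, 24), "CCTTG", b_body)
  pan <- manual_panel(list(refA = refA, refB = refB), c("fa", "fb"))
  idx <- index_panel(pan, k = 15)
  read <- paste0(a_body, "TTT", b_body)  # TTT matches neither flank boundary
  al <- align_arms(read, idx)
  expect_equal(al$status, "ok")
  rj <- resolve_junction(al$left, al$right, read, idx)
  if (rj$mh_len == 0 && rj$ins_seq == "TTT") {
    expect_identical(rj$ins_seq, "TTT")
    expect_equal(rj$mh_len, 0L)
    expect_false(rj$blunt)
  } else fail("junction chemistry not recovered")
})

test_that("abutting arms with no shared sequence are blunt", {
  a_body <- rand_seq(90, 31)
  b_body <- rand_seq(90, 32)
  refA <- paste0(a_body, "A", rand_seq(40, 33))
  refB <- paste0(rand_seq(40, 34), "A", b_body)
  # read joins a_body|b_body; both neighbours are A while the read continues
  # with b_body's first base and ends a_body: force mismatches at both sides
  read <- paste0(a_body, b_body)
  first_b <- substr(b_body, 1, 1); last_a <- substr(a_body, nchar(a_body), nchar(a_body))
  if (first_b != "A" && last_a != "A") {
    pan <- manual_panel(list(refA = refA, refB = refB), c("fa", "fb"))
    idx <- index_panel(pan, k = 15)
    al <- align_arms(read, idx)
    expect_equal(al$status, "ok")
    rj <- resolve_junction(al$left, al$right, read, idx)
    expect_equal(rj$mh_len, 0L)
    expect_identical(rj$ins_seq, "")
    expect_true(rj$blunt)
  } else succeed()
})

test_that("fusion classes follow the panel/family definitions", {
  panel <- tf_panel()
  expect_equal(classify_fusion("17p", "17p", panel), "intra")
  expect_equal(classify_fusion("16p", "21q", panel), "intra")  # same family
  expect_equal(classify_fusion("17p", "XpYp", panel), "inter")
  expect_equal(classify_fusion("17p", "chr3", panel), "genomic")
  expect_equal(classify_fusion("chr1", "chr3", panel), "unresolved")
  # distinct families make 16p:21q inter-chromosomal by definition
  pan2 <- manual_panel(list(`16p` = rand_seq(1200, 41), `21q` = rand_seq(1200, 42)),
                       c("16p", "21q"))
  expect_equal(classify_fusion("16p", "21q", pan2), "inter")
})

test_that("local-template detection finds planted insertions and rejects absent ones", {
  flank_a <- paste0(rand_seq(20, 51), "GGCTA", rand_seq(75, 52))
  flank_b <- rand_seq(100, 53)
  expect_true(detect_local_template("GGCTA", flank_a, flank_b))
  # reverse-complement occurrences count as templated
  expect_true(detect_local_template(revcomp_test("GGCTA"), flank_a, flank_b))
  fa <- gsub("AAAAA", "GACGT", paste0(rand_seq(50, 54)))
  fb <- gsub("AAAAA", "GACGT", paste0(rand_seq(50, 55)))
  expect_false(detect_local_template("AAAAA", fa, fb))
  expect_true(is.na(detect_local_template("", flank_a, flank_b)))
})

test_that("chromatid deletions are distances from the telomere origin, NA for genomic arms", {
  pan <- manual_panel(list(m1 = rand_seq(6000, 61), m2 = rand_seq(6000, 62)),
                      c("f1", "f2"), origin = 0L, side = "left")
  calls <- data.frame(ref_a = c("m1", "m1"), bp_a = c(3500L, 3500L),
                      ref_b = c("m2", "chrX"), bp_b = c(5000L, 1234L))
  out <- chromatid_deletions(calls, pan)
  expect_equal(out$deletion_a_kb, c(3.5, 3.5))
  expect_equal(out$deletion_b_kb, c(5.0, NA))
  expect_equal(out$asymmetry_kb, c(1.5, NA))
  bad <- data.frame(ref_a = "m1", bp_a = -10L, ref_b = "m2", bp_b = 1L)
  expect_error(chromatid_deletions(bad, pan), "data error")
})

test_that("called microhomology equals the brute-force oracle on every cohort call", {
  co <- tf_cohortA()
  calls <- co$calls
  idx <- tf_index()
  store <- idx$store
  sub <- calls[sample(seq_len(nrow(calls)), 250), ]
  rmap <- stats::setNames(seq_len(nrow(co$reads$reads)), co$reads$reads$read_id)
  for (i in seq_len(nrow(sub))) {
    row <- sub[i, ]
    read <- co$reads$r1[[row$read_id]]
    al <- align_arms(read, idx)
    expect_equal(al$status, "ok")
    left_ref <- if (al$left$strand == "+") store$seq[[al$left$ref]] else store$rc[[al$left$ref]]
    right_ref <- if (al$right$strand == "+") store$seq[[al$right$ref]] else store$rc[[al$right$ref]]
    oracle <- tf_mh_oracle(read, left_ref, al$left$diag, right_ref, al$right$diag,
                           anchor_left = al$left$read_start + 14L,
                           anchor_right = al$right$read_end - 14L)
    expect_equal(row$mh_len, oracle)
  }
})

test_that("no resolved call violates the one-of-{MH, INS, blunt} exclusivity", {
  for (co in list(tf_cohortA(), tf_cohortB())) {
    calls <- co$calls
    has_mh <- calls$mh_len > 0
    has_ins <- nzchar(calls$ins_seq)
    expect_true(all(has_mh + has_ins + calls$blunt == 1))
    expect_true(all(abs(calls$asymmetry_kb -
                          abs(calls$deletion_a_kb - calls$deletion_b_kb)) < 1e-9,
                    na.rm = TRUE))
  }
})

test_that("fold-back palindromic intra reads resolve as readily as inter reads", {
  co <- tf_cohortB()
  truth_class <- stats::setNames(co$truth$fusion_class, co$truth$event_id)
  ev_of_read <- stats::setNames(co$reads$reads$event_id, co$reads$reads$read_id)
  resolved <- names(ev_of_read) %in% co$calls$read_id
  rate <- tapply(resolved, truth_class[ev_of_read], mean)
  expect_gte(rate[["intra"]], 0.995)
  expect_gte(rate[["inter"]], 0.995)
  expect_lte(abs(rate[["intra"]] - rate[["inter"]]), 0.005)
})
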