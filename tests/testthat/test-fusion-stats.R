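# Frequencies, summaries and the statistical tests, each checked against an
# independent oracle (hand enumeration or the corresponding stats:: routine).

test_that("fusion frequency follows the per-diploid-genome formula and its scaling laws", {
  expect_equal(fusion_frequency(0, 50)$frequency_per_diploid_genome, 0)
  # 66 ng at 6.6 pg/genome is 10,000 diploid genome equivalents
  expect_equal(fusion_frequency(5, 66)$frequency_per_diploid_genome, 5e-4)
  f1 <- fusion_frequency(7, 33)$frequency_per_diploid_genome
  f2 <- fusion_frequency(7, 66)$frequency_per_diploid_genome
  f3 <- fusion_frequency(14, 33)$frequency_per_diploid_genome
  expect_equal(f2, f1 / 2)   # degree -1 in DNA input
  expect_equal(f3, f1 * 2)   # degree +1 in count
  expect_error(fusion_frequency(5, 0), "positive")
  expect_equal(max_fusion_frequency(c(0, 5, 2), c(66, 66, 66)), 5e-4)
})

test_that("class proportions partition to one and match the simulated mixture", {
  toy <- data.frame(fusion_class = c("intra", "intra", "inter", "genomic"))
  cp <- class_proportions(toy)
  expect_equal(cp$proportion[cp$fusion_class == "intra"], 0.5)
  expect_equal(cp$proportion[cp$fusion_class == "inter"], 0.25)
  expect_equal(cp$proportion[cp$fusion_class == "genomic"], 0.25)
  expect_equal(sum(cp$proportion), 1)
  expect_error(class_proportions(data.frame(fusion_class = "unresolved")),
               "no resolved calls")

  co <- tf_cohortA()
  cp2 <- class_proportions(co$calls)
  for (cl in c("intra", "inter", "genomic")) {
    ci <- tf_binom99(co$cfg$class_mixture[[cl]], nrow(co$calls))
    got <- cp2$proportion[cp2$fusion_class == cl]
    expect_gte(got, ci["lo"] - 3 / nrow(co$calls))
    expect_lte(got, ci["hi"] + 3 / nrow(co$calls))
  }
})

test_that("junction summaries are per-class independent and correct on degenerate input", {
  blunt_calls <- data.frame(fusion_class = "inter", mh_len = 0L,
                            ins_seq = "", ins_templated = NA, blunt = TRUE)
  s <- suppressWarnings(summarize_junctions(blunt_calls))
  expect_equal(s$prop_blunt, 1)
  expect_equal(s$prop_mh + s$prop_ins, 0)

  co <- tf_cohortA()
  s_all <- summarize_junctions(co$calls)
  modified <- co$calls
  keep <- modified$fusion_class != "genomic"
  s_sub <- suppressWarnings(summarize_junctions(modified[keep, , drop = FALSE]))
  a <- s_all[s_all$group == "intra", ]; b <- s_sub[s_sub$group == "intra", ]
  for (col in c("n", "prop_mh", "prop_ins", "prop_blunt", "mean_mh_bp",
                "mean_ins_bp", "templated_fraction"))
    expect_equal(unname(a[[col]]), unname(b[[col]]))
  expect_true(all(abs(s_all$prop_mh + s_all$prop_ins + s_all$prop_blunt - 1) < 1e-9))
})

test_that("the recovered mean microhomology length sits in its CLT band", {
  # dedicated MH-only cohort of 2,000 junction lengths, summarized from truth
  panel <- tf_panel()
  cfg <- fusion_sim_config(n_events = 2000, ins_fraction = 0, blunt_fraction = 0,
                           mh_length_distribution = dist_mh_geometric(4),
                           class_mixture = c(intra = 0.5, inter = 0.5, genomic = 0),
                           seed = 404)
  tr <- simulate_fusion_events(panel, NULL, cfg)
  pseudo <- data.frame(fusion_class = tr$fusion_class, mh_len = tr$mh_len,
                       ins_seq = tr$ins_seq, ins_templated = tr$ins_templated,
                       blunt = tr$mh_len == 0 & !nzchar(tr$ins_seq))
  s <- suppressWarnings(summarize_junctions(pseudo, by_class = FALSE))
  expect_lte(abs(s$mean_mh_bp - 4.0), 0.15)
  mu <- dist_mean(cfg$mh_length_distribution)
  sdv <- dist_sd(cfg$mh_length_distribution)
  expect_lte(abs(s$mean_mh_bp - mu), 2.576 * sdv / sqrt(2000))
})

test_that("Fisher p-values match hand enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  # margins (2,2)x(2,2): P(k=0) = P(k=2) = 1/6, two-sided sum = 1/3
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)), 1 / 3)
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(p0, 1)
  withr::with_seed(1, {
    for (i in 1:200) {
      tb <- matrix(rpois(4, 6) + 1, 2)
      expect_lt(abs(fisher_exact_2x2(tb) - stats::fisher.test(tb)$p.value), 1e-9)
    }
  })
})

test_that("Yates-corrected chi-squared matches the textbook formula and stats::chisq.test", {
  r <- chi_squared_yates(matrix(10, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  withr::with_seed(2, {
    for (i in 1:100) {
      tb <- matrix(rpois(4, 20) + 1, 2)
      ours <- chi_squared_yates(tb)
      expect_equal(ours$statistic, chi_squared_yates(t(tb))$statistic)
      n <- sum(tb); rs <- rowSums(tb); cs <- colSums(tb)
      ref_stat <- n * max(0, abs(tb[1, 1] * tb[2, 2] - tb[1, 2] * tb[2, 1]) - n / 2)^2 /
        prod(c(rs, cs))
      expect_lt(abs(ours$statistic - ref_stat), 1e-10)
      expect_lt(abs(ours$p_value - stats::chisq.test(tb, correct = TRUE)$p.value),
                1e-10)
    }
  })
  expect_error(chi_squared_yates(matrix(c(0, 0, 1, 1), 2)), "expected")
})

test_that("Mann-Whitney enumeration reproduces hand counts and is rank-invariant", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3)), 1)
  # complete separation of 3 vs 3: U = 0, one of 20 assignments per tail
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6)), 0.1)
  x <- c(1.2, 3.4, 2.2, 5.5); y <- c(2.1, 7.2, 6.6)
  expect_equal(mann_whitney_u(x, y), mann_whitney_u(exp(x), exp(y)))
  withr::with_seed(3, {
    for (i in 1:50) {
      x <- round(stats::runif(sample(3:8, 1), 0, 50), 1)
      y <- round(stats::runif(sample(3:8, 1), 0, 50), 1)
      if (any(duplicated(c(x, y)))) next  # wilcox.test abandons exactness on ties
      expect_equal(mann_whitney_u(x, y),
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
  expect_error(mann_whitney_u(c(1, 2), c(3, 4, 5)), "at least 3")
})

test_that("signed-rank enumeration reproduces hand counts and pair-order invariance", {
  expect_warning(p0 <- wilcoxon_signed_rank(rep(0, 8)), "all differences")
  expect_equal(p0, 1)
  # five positive differences: one extreme sign pattern of 32 per tail
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5)), 0.0625)
  d <- c(1.5, -2.5, 3.5, 4.5, -0.5, 6.5)
  expect_equal(wilcoxon_signed_rank(d), wilcoxon_signed_rank(rev(d)))
  withr::with_seed(4, {
    for (i in 1:40) {
      d <- round(stats::runif(sample(6:12, 1), -10, 10), 2)
      d <- d[d != 0]
      if (length(d) < 5 || any(duplicated(abs(d)))) next
      expect_equal(wilcoxon_signed_rank(d),
                   stats::wilcox.test(d, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
  expect_error(wilcoxon_signed_rank(c(0, 0, 0, 1, 2)), "fewer than 5")
})

test_that("chromosome enrichment conserves expectation and matches exact binomial tails", {
  cl <- c(A = 1000, B = 1000)
  even <- chromosome_enrichment(rep(c("A", "B"), each = 5), cl)
  expect_equal(even$expected, c(5, 5))
  expect_equal(even$p_value, c(1, 1))
  skew <- chromosome_enrichment(rep("A", 10), cl)
  expect_equal(skew$p_value[skew$chrom == "B"], 2 * 2^-10)
  expect_equal(sum(skew$expected), 10)
  expect_error(chromosome_enrichment(c("A", "Z"), cl), "unknown chromosome")
  # cross-check the central two-sided binomial against stats::binom.test
  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(20:200, 1); p <- stats::runif(1, 0.05, 0.5)
      k <- stats::rbinom(1, n, p)
      expect_equal(binom_test_2sided(k, n, p),
                   stats::binom.test(k, n, p)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("feature coincidence honours half-open intervals and the uniform null rate", {
  track <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 200))  # [100,200)
  inside <- feature_coincidence(data.frame(chrom = "c1", pos = 150), track)
  expect_equal(inside$coincident, 1L)
  boundary <- feature_coincidence(data.frame(chrom = "c1", pos = 200), track)
  expect_equal(boundary$coincident, 0L)
  at_start <- feature_coincidence(data.frame(chrom = "c1", pos = 100), track)
  expect_equal(at_start$coincident, 1L)

  cl <- c(c1 = 100000)
  cover <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 10000))  # 10%
  np <- simulate_null_junction_positions(10000, cl, seed = 9)
  fc <- feature_coincidence(np, cover)
  ci <- tf_binom99(0.10, 10000)
  expect_gte(fc$proportion, ci["lo"])
  expect_lte(fc$proportion, ci["hi"])

  cmp <- compare_coincidence(5, 50, 500, 10000, method = "auto")
  expect_equal(cmp$test_name, "chi_squared_yates")
  cmp2 <- compare_coincidence(5, 50, 10, 60, method = "auto")
  expect_equal(cmp2$test_name, "fisher_exact")
})

test_that("growth divergence equals the control-minus-clone OLS slope difference", {
  ctrl <- data.frame(time_days = 0:9, population_doublings = 0:9 * 1.0)
  clone <- data.frame(time_days = 0:9, population_doublings = 0:9 * 0.6)
  gd <- growth_divergence(clone, ctrl)
  expect_equal(gd$divergence, 0.4)
  expect_equal(growth_divergence(ctrl, ctrl)$divergence, 0)
  withr::with_seed(6, {
    t <- sort(stats::runif(8, 0, 30))
    y <- 0.7 * t + stats::rnorm(8, 0, 0.5)
    d <- data.frame(time_days = t, population_doublings = y)
    closed <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    expect_lt(abs(growth_divergence(d, d)$clone_slope - closed), 1e-12)
  })
  expect_error(growth_divergence(clone[1:2, ], ctrl), "3 time points")
  flat <- data.frame(time_days = rep(1, 4), population_doublings = 1:4)
  expect_error(growth_divergence(flat, ctrl), "degenerate")
})
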