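# Exact and rank-based tests used throughout the comparative analyses.
# These are implemented here under the conventions the analyses require
# (two-sided p by summing outcomes no more probable than the observed one,
# fixed enumeration thresholds); base R's implementations serve as
# independent cross-checks in the test suite.

#' Fisher's exact test for a 2x2 table (two-sided, enumeration)
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of outcomes no more probable than the
#' observed table (relative tolerance 1e-7).
#'
#' @param table A 2x2 matrix (or something coercible) of non-negative counts.
#' @return Two-sided p-value. A zero margin is degenerate: p = 1 with warning.
#' @examples
#' fisher_exact_2x2(matrix(c(17, 277, 0, 103), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  stopifnot(all(dim(tb) == 2L), all(tb >= 0), all(tb == round(tb)))
  rs <- rowSums(tb); cs <- colSums(tb)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate table (zero margin): p = 1")
    return(1)
  }
  n <- sum(tb)
  k_obs <- tb[1, 1]
  k <- max(0L, rs[1] + cs[1] - n):min(rs[1], cs[1])
  pr <- stats::dhyper(k, cs[1], n - cs[1], rs[1])
  p_obs <- stats::dhyper(k_obs, cs[1], n - cs[1], rs[1])
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Chi-squared test with Yates' continuity correction for a 2x2 table
#'
#' Used instead of Fisher's exact test when one group is a large simulated
#' dataset. The statistic is clamped at zero when the correction exceeds the
#' deviation; p is from the chi-squared survival function with 1 df.
#'
#' @param table A 2x2 matrix of non-negative counts; all expected cells must
#'   be positive.
#' @return List with `statistic` and `p_value`.
#' @export
chi_squared_yates <- function(table) {
  tb <- as.matrix(table)
  stopifnot(all(dim(tb) == 2L), all(tb >= 0))
  rs <- rowSums(tb); cs <- colSums(tb); n <- sum(tb)
  if (any(outer(rs, cs) / n <= 0))
    stop("input error: zero expected cell")
  num <- max(0, abs(tb[1, 1] * tb[2, 2] - tb[1, 2] * tb[2, 1]) - n / 2)^2 * n
  stat <- num / (rs[1] * rs[2] * cs[1] * cs[2])
  list(statistic = unname(stat),
       p_value = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE))
}

#' Mann-Whitney unpaired U-test (two-sided)
#'
#' Exact by enumeration of all group assignments when the combined sample
#' size is at most 20 (ties handled through midranks); otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples, each with at least 3 observations.
#' @return Two-sided p-value.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 3 || length(y) < 3)
    stop("input error: each group needs at least 3 observations")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  eps <- 1e-9
  if (N <= 20) {
    sel <- utils::combn(N, m)
    u_all <- colSums(matrix(r[sel], nrow = m)) - m * (m + 1) / 2
    p_lo <- mean(u_all <= u_obs + eps)
    p_hi <- mean(u_all >= u_obs - eps)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- m * n / 2
  ties <- table(r)
  sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) { warning("all observations tied"); return(1) }
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon matched-pairs signed-rank test (two-sided)
#'
#' Zero differences are dropped (their count is reported via a message when
#' any are present). Exact by enumeration of all sign patterns when at most
#' 15 non-zero differences remain, otherwise a normal approximation with tie
#' and continuity corrections.
#'
#' @param x Numeric vector of first measurements, or of differences when `y`
#'   is NULL.
#' @param y Optional paired second measurements.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  nz <- d[d != 0]
  n_zero <- length(d) - length(nz)
  if (length(nz) == 0) {
    warning("degenerate: all differences are zero; p = 1")
    return(1)
  }
  if (n_zero > 0)
    message(n_zero, " zero difference(s) dropped")
  if (length(nz) < 5)
    stop("input error: fewer than 5 non-zero differences")
  n <- length(nz)
  r <- rank(abs(nz))
  v_obs <- sum(r[nz > 0])
  eps <- 1e-9
  if (n <= 15) {
    signs <- matrix(as.integer(intToBits(0:(2^n - 1L))), nrow = 32L)[seq_len(n), , drop = FALSE]
    v_all <- as.numeric(crossprod(signs, r))
    p_lo <- mean(v_all <= v_obs + eps)
    p_hi <- mean(v_all >= v_obs - eps)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v_obs - mu - sign(v_obs - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Two-sided exact binomial p-value (minimum-likelihood convention)
#'
#' Sums the probabilities of all outcomes no more probable than the observed
#' count, mirroring the Fisher convention; used by the per-chromosome
#' enrichment test.
#'
#' @param k Observed count.
#' @param n Number of trials.
#' @param p Null success probability.
#' @export
binom_test_2sided <- function(k, n, p) {
  d <- stats::dbinom(0:n, n, p)
  min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
}
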