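#' Distribution objects for the synthetic-data generators
#'
#' Small self-describing distribution objects used to configure the fusion
#' simulator: discrete length distributions (microhomology, insertion length)
#' and continuous deletion distributions. Each object carries enough to be
#' sampled with [rdist()] and to report exact moments with [dist_mean()] and
#' [dist_sd()], so that recovery tests can center their confidence intervals
#' on the true configured mean.
#'
#' @param values Integer support of a discrete distribution.
#' @param prob Probabilities (recycled/normalized to sum to 1).
#' @return An object of class `fuseq_dist`.
#' @examples
#' d <- dist_discrete(1:6, rep(1, 6))
#' dist_mean(d)
#' @export
dist_discrete <- function(values, prob = rep(1, length(values))) {
  stopifnot(length(values) >= 1, length(prob) == length(values), all(prob >= 0), sum(prob) > 0)
  structure(list(kind = "discrete", values = as.numeric(values), prob = prob / sum(prob)),
            class = "fuseq_dist")
}

#' Truncated geometric microhomology-length distribution with an exact mean
#'
#' Geometric distribution on `min:max` whose success parameter is solved
#' numerically so that the *truncated* mean equals `mean` exactly. This keeps
#' the configured mean honest after capping the support (long exact
#' microhomologies cannot be realized on fixed random references).
#'
#' @param mean Target mean length in bp.
#' @param min,max Integer support bounds. The default ceiling of 10 bp keeps
#'   every requested length realizable on fixed references (exact joint
#'   matches much beyond that are combinatorially absent from a few hundred
#'   kb of sequence) while covering the microhomology lengths seen at
#'   end-joining junctions.
#' @export
dist_mh_geometric <- function(mean = 4, min = 1L, max = 10L) {
  stopifnot(mean > min, mean < max)
  v <- min:max
  trunc_mean <- function(p) {
    w <- p * (1 - p)^(v - min)
    sum(v * w) / sum(w)
  }
  p <- stats::uniroot(function(p) trunc_mean(p) - mean, c(1e-6, 1 - 1e-6))$root
  dist_discrete(v, p * (1 - p)^(v - min))
}

#' Truncated gamma distribution (continuous, non-negative)
#'
#' Used for chromatid deletion sizes in kb. Sampling is by rejection against
#' the truncation bound.
#' @param shape,scale Gamma parameters.
#' @param max Upper truncation bound (resampled above it).
#' @export
dist_gamma_trunc <- function(shape = 2, scale = 1, max = 4.5) {
  stopifnot(shape > 0, scale > 0, max > 0)
  structure(list(kind = "gamma_trunc", shape = shape, scale = scale, max = max),
            class = "fuseq_dist")
}

#' Continuous uniform distribution
#' @param min,max Bounds.
#' @export
dist_uniform <- function(min = 0, max = 1) {
  stopifnot(max > min)
  structure(list(kind = "uniform", min = min, max = max), class = "fuseq_dist")
}

#' Sample from a distribution object
#' @param d A `fuseq_dist` object.
#' @param n Number of draws.
#' @export
rdist <- function(d, n) {
  stopifnot(inherits(d, "fuseq_dist"), n >= 0)
  switch(d$kind,
    discrete = if (length(d$values) == 1L) rep(d$values, n) else
      sample(d$values, n, replace = TRUE, prob = d$prob),
    gamma_trunc = {
      x <- stats::rgamma(n, shape = d$shape, scale = d$scale)
      while (any(bad <- x > d$max))
        x[bad] <- stats::rgamma(sum(bad), shape = d$shape, scale = d$scale)
      x
    },
    uniform = stats::runif(n, d$min, d$max),
    stop("unknown distribution kind: ", d$kind)
  )
}

#' Exact mean of a distribution object
#' @param d A `fuseq_dist` object.
#' @export
dist_mean <- function(d) {
  stopifnot(inherits(d, "fuseq_dist"))
  switch(d$kind,
    discrete = sum(d$values * d$prob),
    gamma_trunc = {
      # mean of gamma truncated to [0, max]
      f <- function(x) x * stats::dgamma(x, shape = d$shape, scale = d$scale)
      stats::integrate(f, 0, d$max)$value / stats::pgamma(d$max, shape = d$shape, scale = d$scale)
    },
    uniform = (d$min + d$max) / 2
  )
}

#' Exact standard deviation of a distribution object
#' @param d A `fuseq_dist` object.
#' @export
dist_sd <- function(d) {
  stopifnot(inherits(d, "fuseq_dist"))
  m <- dist_mean(d)
  m2 <- switch(d$kind,
    discrete = sum(d$values^2 * d$prob),
    gamma_trunc = {
      f <- function(x) x^2 * stats::dgamma(x, shape = d$shape, scale = d$scale)
      stats::integrate(f, 0, d$max)$value / stats::pgamma(d$max, shape = d$shape, scale = d$scale)
    },
    uniform = (d$max - d$min)^2 / 12 + m^2
  )
  sqrt(m2 - m^2)
}

#' @export
print.fuseq_dist <- function(x, ...) {
  cat("<fuseq_dist:", x$kind, "> mean =", signif(dist_mean(x), 4),
      "sd =", signif(dist_sd(x), 4), "\n")
  invisible(x)
}
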