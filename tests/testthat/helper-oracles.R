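# Independent oracles used to cross-check the package implementation.

# Plain bisection on the sequential-binding mass balance, written from
# the equilibrium definition (no package internals).
oracleFreeL <- function(kd, ptot, ltot, tol = 1e-12) {
  if (ltot == 0) return(0)
  frac <- function(L) {
    terms <- c(1, cumprod(L / kd))
    terms / sum(terms)
  }
  f <- function(L) {
    x <- frac(L)
    L + ptot * sum(seq_along(kd) * x[-1]) - ltot
  }
  lo <- 0; hi <- ltot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(1, ltot)) break
  }
  (lo + hi) / 2
}

# Brute-force residue-set union for coverage.
oracleCoverage <- function(peptides, seqLength) {
  covered <- unique(unlist(Map(seq.int, peptides$start, peptides$end)))
  list(coverage = 100 * length(covered) / seqLength,
       redundancy = sum(peptides$end - peptides$start + 1) / length(covered))
}

# Expected m/z of a protonated species.
mzFor <- function(M, z) (M + z * 1.00728) / z

# Build a synthetic profile PeakList directly from a peak inventory
# (Gaussian shapes, no noise) without going through the generator.
profileFrom <- function(mzs, heights, sigma = 2, step = 0.1) {
  grid <- seq(min(mzs) - 8 * sigma, max(mzs) + 8 * sigma, by = step)
  y <- rep(0, length(grid))
  for (i in seq_along(mzs))
    y <- y + heights[i] * exp(-((grid - mzs[i])^2) / (2 * sigma^2))
  peakList(grid, y)
}
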