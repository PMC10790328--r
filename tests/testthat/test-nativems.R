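test_that("peak picking centroids symmetric peaks and merges close ones", {
  pl <- profileFrom(3000, 100)
  cen <- pickPeaks(pl, minSnr = 3, minSpacing = 5)
  expect_length(peakMz(cen), 1)
  expect_equal(peakMz(cen), 3000, tolerance = 0.1 / 3000)
  # two Gaussians closer than minSpacing merge into one centroid
  pl2 <- profileFrom(c(3000, 3003), c(100, 100))
  cen2 <- pickPeaks(pl2, minSnr = 3, minSpacing = 5)
  expect_length(peakMz(cen2), 1)
  # an all-zero trace yields an empty result, not an error
  z <- peakList(seq(1000, 1010, 0.5), rep(0, 21))
  expect_length(peakMz(pickPeaks(z)), 0)
})

test_that("picked centroid count matches the generator's peak inventory", {
  # threshold chosen so no two surviving (z, k) peaks overlap in m/z
  sp <- spectrumPreset("fl", fractions = list(c(0.4, 0.35, 0.15, 0.07, 0.03)),
                       noiseFloor = 0)
  g <- genSpectrum(sp, seed = 1, threshold = 0.03)
  expect_gt(min(diff(sort(g$inventory$mz))), 10)
  cen <- pickPeaks(g$profile, minSnr = 3, minSpacing = 10)
  expect_length(peakMz(cen), nrow(g$inventory))
})

test_that("charge-series deconvolution inverts the m/z construction", {
  z <- 14:17
  pl <- peakList(mzFor(58000, z), rep(100, length(z)))
  res <- deconvolveMass(pl, zRange = c(12, 20))
  expect_equal(res[[1]]@mass, 58000, tolerance = 0.5 / 58000)
  expect_identical(res[[1]]@charges, z)
  # a deleted charge state leaves a gap but the same mass
  pl2 <- peakList(mzFor(58000, c(14, 15, 17)), rep(100, 3))
  res2 <- deconvolveMass(pl2, zRange = c(12, 20))
  expect_equal(res2[[1]]@mass, 58000, tolerance = 0.5 / 58000)
  expect_identical(res2[[1]]@charges, c(14L, 15L, 17L))
  # too few matchable peaks: empty result with diagnostic
  bad <- peakList(c(1000, 2000, 3500), c(1, 1, 1))
  out <- deconvolveMass(bad, zRange = c(12, 20))
  expect_length(out, 0)
  expect_match(attr(out, "diagnostic"), "no candidate")
})

test_that("two interleaved series are both recovered as top assignments", {
  zA <- 14:19; zB <- 12:16
  pl <- peakList(c(mzFor(58000, zA), mzFor(48200, zB)),
                 c(rep(80, length(zA)), rep(60, length(zB))))
  res <- deconvolveMass(pl, zRange = c(10, 22))
  top2 <- sort(vapply(res[1:2], function(s) s@mass, 0))
  expect_equal(top2, c(48200, 58000), tolerance = 0.5 / 48200)
})

test_that("deconvolution round-trip holds across the charge range", {
  set.seed(21)
  for (i in 1:8) {
    M <- runif(1, 45000, 65000)
    sp <- spectrumPreset("fl", fractions = list(1))
    sp@masses <- c(p = M)
    sp@zCenter <- 17; sp@zRange <- c(12L, 22L)
    g <- genSpectrum(sp, seed = i)
    cen <- pickPeaks(g$profile, minSnr = 5, minSpacing = 10)
    res <- deconvolveMass(cen, zRange = c(12, 22))
    expect_lt(abs(res[[1]]@mass - M), 0.5)
  }
})

test_that("adduct ladders are assigned to the right stoichiometries", {
  pi_m <- lipidMass("PI")
  z <- 15:18
  M <- 58000
  mzs <- unlist(lapply(0:2, function(k) mzFor(M + k * pi_m, z)))
  pl <- peakList(mzs, rep(50, length(mzs)))
  base <- deconvolveMass(pl, zRange = c(12, 20))[[1]]
  ad <- assignLipidAdducts(pl, base, lipidTable()[lipidTable()$class == "PI", ])
  ks <- sort(unique(ad@assignments$k))
  expect_identical(ks, 0:2)
  expect_true(all(abs(ad@assignments$residual) <= 3))
  # apo-only spectrum: all stoichiometries zero
  pl0 <- peakList(mzFor(M, z), rep(50, 4))
  base0 <- deconvolveMass(pl0, zRange = c(12, 20))[[1]]
  ad0 <- assignLipidAdducts(pl0, base0, lipidTable())
  expect_true(all(ad0@assignments$k == 0))
})

test_that("the four-lipid competition ladder resolves without cross-talk", {
  pips <- lipidTable()[lipidTable()$class %in% c("PI", "PI4P", "PIP2", "PIP3"), ]
  z <- 16:18
  M <- 58000
  mzs <- c(mzFor(M, z), unlist(lapply(pips$average_mass,
                                      function(m) mzFor(M + m, z))))
  pl <- peakList(sort(mzs), rep(40, length(mzs)))
  base <- deconvolveMass(pl, zRange = c(14, 20))[[1]]
  ad <- assignLipidAdducts(pl, base, pips, tol = 3)
  a <- ad@assignments[ad@assignments$k == 1, ]
  expect_setequal(unique(a$lipid), pips$name)
  expect_false(any(a$ambiguous))
  # each lipid claims exactly one peak per charge state
  expect_identical(as.integer(table(a$lipid)), rep(length(z), 4L))
})

test_that("mole fractions normalize, and are scale and order invariant", {
  mkAssign <- function(int) {
    new("AdductAssignment", baseMass = 58000,
        assignments = data.frame(charge = 17L, peakIndex = seq_along(int),
                                 lipid = c(NA, "PI(18:1/18:1)", "PI(18:1/18:1)"),
                                 k = 0:2, mz = 1, intensity = int,
                                 residual = 0, ambiguous = FALSE),
        maxStoichiometry = 4L)
  }
  mf <- moleFractions(mkAssign(c(50, 30, 20)))
  expect_equal(unname(unlist(mf[paste0("x", 0:2)])), c(0.5, 0.3, 0.2))
  expect_equal(sum(mf[-1]), 1, tolerance = 1e-9)
  # uniform intensity scaling leaves fractions unchanged
  mfScaled <- moleFractions(mkAssign(c(50, 30, 20) * 1e4))
  expect_equal(unlist(mf[-1]), unlist(mfScaled[-1]))
  # all-apo
  mfApo <- moleFractions(mkAssign(c(10, 0, 0)))
  expect_equal(mfApo$x0, 1)
  expect_error(moleFractions(mkAssign(c(0, 0, 0))), "zero total")
})

test_that("full generator round-trip recovers the input fractions", {
  fr <- c(0.4, 0.35, 0.15, 0.07, 0.03)
  sp <- spectrumPreset("fl", fractions = list(fr))
  g <- genSpectrum(sp, seed = 2)
  cen <- pickPeaks(g$profile, minSnr = 5, minSpacing = 10)
  base <- deconvolveMass(cen, zRange = c(12, 22))[[1]]
  ad <- assignLipidAdducts(cen, base,
                           lipidTable()[lipidTable()$class == "PI", ])
  mf <- moleFractions(ad)
  expect_true(all(abs(unlist(mf[paste0("x", 0:4)]) - fr) <= 0.02))
})

test_that("adduct assignment is stable under peak-order permutation", {
  pi_m <- lipidMass("PI")
  z <- 15:17
  mzs <- unlist(lapply(0:3, function(k) mzFor(58000 + k * pi_m, z)))
  ints <- rep(c(40, 30, 20, 10), each = length(z))
  set.seed(5); perm <- sample(seq_along(mzs))
  plA <- peakList(mzs, ints)
  plB <- peakList(mzs[perm], ints[perm])   # constructor re-sorts
  base <- deconvolveMass(plA, zRange = c(12, 20))[[1]]
  pis <- lipidTable()[lipidTable()$class == "PI", ]
  a <- assignLipidAdducts(plA, base, pis)
  b <- assignLipidAdducts(plB, base, pis)
  expect_equal(moleFractions(a), moleFractions(b))
})

test_that("competition comparison ranks lipids and tests pairs", {
  # equilibrium oracle: equimolar competition occupancy ~ 1/K_D1; the
  # high-affinity species must rank first
  set.seed(31)
  kd1 <- c(PI = 6, PI4P = 6, PIP2 = 0.7, PIP3 = 6)
  occ <- (1 / kd1) / sum(1 / kd1)
  ints <- lapply(occ, function(o) o * 100 * (1 + rnorm(3, 0, 0.03)))
  cmp <- competitionCompare(ints)
  expect_identical(cmp$summary$lipid[1], "PIP2")
  expect_identical(cmp$summary$rank[1], 1L)
  # hand case: (3,4,5) vs (13,14,15) differs at p < 0.01
  cmp2 <- competitionCompare(list(a = c(3, 4, 5), b = c(13, 14, 15)))
  expect_lt(cmp2$pairwise$p, 0.01)
  expect_match(cmp2$pairwise$stars, "\\*")
  # identical replicate sets: p = 1, no stars
  cmp3 <- competitionCompare(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(cmp3$pairwise$p, 1)
  expect_identical(cmp3$pairwise$stars, "ns")
  expect_error(competitionCompare(list(a = 1:3, b = 1:2)), "unequal")
})

test_that("mixture bound/apo ratios follow the occupancy oracle", {
  df <- data.frame(protein = rep(c("fl", "trunc"), each = 3),
                   replicate = rep(1:3, 2),
                   apo = c(100, 98, 102, 100, 101, 99),
                   bound = c(100, 99, 101, 20, 21, 19))
  res <- mixtureBoundRatio(df)
  s <- res$summary
  expect_gt(s$meanRatio[s$protein == "fl"], s$meanRatio[s$protein == "trunc"])
  expect_lt(res$p, 0.001)
  # equal bound and apo intensities: ratio 1 for both; identical ratios
  # across proteins have zero variance and are flagged degenerate
  dfEq <- data.frame(protein = rep(c("A", "B"), each = 3),
                     replicate = rep(1:3, 2), apo = 50, bound = 50)
  expect_warning(resEq <- mixtureBoundRatio(dfEq), "degenerate")
  expect_true(all(resEq$summary$meanRatio == 1))
  expect_true(is.na(resEq$p))
  dfBad <- df; dfBad$apo[1] <- NA
  expect_error(mixtureBoundRatio(dfBad), "apo")
})
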