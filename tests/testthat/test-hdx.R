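test_that("maximum uptake follows the amide-counting convention", {
  expect_identical(maxUptake("LLGNDAVKKL"), 9L)   # 10-mer, no proline
  expect_identical(maxUptake("APGI"), 2L)          # proline at position 2
  expect_identical(maxUptake("P"), 0L)             # unusable
  expect_identical(maxUptake("PAGI"), 3L)          # leading proline ignored
  expect_error(maxUptake("AXG"), "non-standard")
})

test_that("RFU is uptake over N_max with propagated SD", {
  u <- expand.grid(replicate = 1:3, state = "apo", exposure = c(1, 60))
  u$start <- 1; u$end <- 10; u$sequence <- "LLGNDAVKKL"
  u$uptake <- ifelse(u$exposure == 1, 4.5, 0)
  ds <- hdxDataset(u, exposures = c(1, 60))
  rfu <- computeRfu(ds)
  expect_equal(rfu$rfu[rfu$exposure == 1], 0.5)
  expect_equal(rfu$rfu[rfu$exposure == 60], 0)
  expect_equal(rfu$sd, c(0, 0))
  # single replicate is an error
  expect_error(computeRfu(hdxDataset(u[u$replicate == 1, ],
                                     exposures = c(1, 60))),
               "fewer than 2")
})

test_that("generator RFU matches the closed-form exchange average", {
  pre <- hdxPreset("null", noiseSd = 0)
  ds <- genHdx(pre, seed = 1, states = "apo")
  truth <- attr(ds, "truth")
  rfu <- suppressWarnings(computeRfu(ds))
  pep <- peptideTable(ds)
  for (i in c(1, 25, 60)) {
    row <- rfu[rfu$start == pep$start[i] & rfu$end == pep$end[i] &
               rfu$exposure == 360, ]
    tr <- truth[truth$start == pep$start[i] & truth$end == pep$end[i] &
                truth$exposure == 360, ]
    expect_equal(row$rfu, tr$uptake / pep$nmax[i], tolerance = 1e-9)
  }
  # synthetic RFU stays in [0, 1] and is monotone in exposure
  expect_true(all(rfu$rfu >= 0 & rfu$rfu <= 1))
  byPep <- split(rfu, paste(rfu$start, rfu$end))
  for (b in byPep)
    expect_true(all(diff(b$rfu[order(b$exposure)]) >= -1e-9))
})

test_that("differential uptake reproduces the gate-opening sign pattern", {
  ds <- genHdx(hdxPreset("synergy"), seed = 3)
  dS <- deltaRfu(ds, "S1P")
  # identical-state null: apo vs apo relabeled
  u <- uptakeTable(ds)
  apo2 <- u[u$state == "apo", ]; apo2$state <- "S1P"
  dsNull <- hdxDataset(rbind(u[u$state == "apo", ], apo2))
  dNull <- deltaRfu(dsNull, "S1P")
  expect_true(all(dNull$dRFU == 0))
  expect_true(all(!dNull$significant))
  # substrate binding: rapid protection at TM8 (<1 min)
  tm8 <- dS[dS$exposure == 1 & dS$start >= 349 & dS$end <= 372, ]
  expect_true(all(tm8$dRFU < 0))
  expect_true(all(tm8$significant))
  # late positive differential at the extracellular gate peptides:
  # positive at every late exposure, significant at one or more (loop
  # peptides saturate at the longest times; short peptides are noisier)
  late <- dS[dS$exposure %in% c(60, 180, 360), ]
  for (pp in list(c(117, 126), c(127, 142), c(143, 147), c(335, 340))) {
    sel <- late[late$start == pp[1] & late$end == pp[2], ]
    expect_true(all(sel$dRFU > 0))
    expect_true(any(sel$significant))
  }
  # the late deprotection is confined to the gate: no substantial
  # significant positive differential away from the affected segments
  # (isolated small-magnitude false positives are expected at per-cell
  # alpha = 0.05 without multiplicity correction)
  topo <- transporterTopology()
  aff <- topo[topo$region %in% c("TM1_ext", "L1-2", "TM2_ext", "TM7_ext",
                                 "TM8"), ]
  overlaps <- vapply(seq_len(nrow(late)), function(i)
    any(late$start[i] <= aff$end & late$end[i] >= aff$start), TRUE)
  outside <- late[!overlaps, ]
  expect_true(all(!(outside$significant & outside$dRFU > 0.05)))
})

test_that("phosphoinositide binding protects the cytoplasmic face and
           deprotects the extracellular side", {
  ds <- genHdx(hdxPreset("synergy"), seed = 3)
  dP <- deltaRfu(ds, "PIP2")
  early <- function(s, e) dP[dP$start == s & dP$end == e & dP$exposure == 1, ]
  late <- function(s, e) dP[dP$start == s & dP$end == e & dP$exposure == 60, ]
  # rapid protection at the N terminus and the cytoplasmic side of TM2
  expect_lt(early(28, 34)$dRFU, 0)
  expect_true(early(28, 34)$significant)
  expect_lt(early(158, 164)$dRFU, 0)
  # allosteric late deprotection on the extracellular side of TM2
  lateTm2 <- dP[dP$start == 143 & dP$end == 147 &
                dP$exposure %in% c(60, 180, 360), ]
  expect_true(all(lateTm2$dRFU > 0))
  expect_true(any(lateTm2$significant))
})

test_that("delta-RFU type-I error is controlled under the null", {
  ps <- numeric()
  for (s in 1:10) {
    dn <- genHdx(hdxPreset("null"), seed = s, states = c("apo", "S1P"))
    d <- deltaRfu(dn, "S1P")
    ps <- c(ps, d$p[d$exposure == 60])
  }
  expect_gte(length(ps), 1000)
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("synergy is null on additive data and positive at the gate", {
  da <- genHdx(hdxPreset("additive"), seed = 4)
  sa <- synergy(da)
  s60 <- sa[sa$exposure == 60, ]
  se <- sd(s60$S) / sqrt(nrow(s60))
  expect_lt(abs(mean(s60$S)), 2 * se)
  ds <- genHdx(hdxPreset("synergy"), seed = 4)
  ss <- synergy(ds)
  g60 <- ss[ss$exposure == 60, ]
  # the four marker peptides of the gate all respond super-additively
  for (pp in list(c(117, 126), c(259, 263), c(336, 340), c(470, 478)))
    expect_gt(g60$S[g60$start == pp[1] & g60$end == pp[2]], 0)
  # pooled over peptides inside gate segments the effect is significant
  topo <- transporterTopology()
  gate <- topo[topo$region %in% c("TM1_ext", "TM2_ext", "TM6_ext",
                                  "TM7_ext", "TM11_ext", "TM12_ext"), ]
  inGate <- vapply(seq_len(nrow(g60)), function(i)
    any(g60$start[i] >= gate$start & g60$end[i] <= gate$end), TRUE)
  gateS <- g60$S[inGate]
  expect_gt(length(gateS), 3)
  expect_lt(t.test(gateS, alternative = "greater")$p.value, 0.001)
  # away from the gate the statistic is centered on zero
  offS <- g60$S[!inGate & g60$start > 370]
  expect_lt(abs(mean(offS)), 3 * sd(offS) / sqrt(length(offS)))
})

test_that("coverage statistics agree with a brute-force residue union", {
  expect_equal(coverageStats(data.frame(start = 1, end = 50), 100)$coverage,
               50)
  cs <- coverageStats(data.frame(start = c(1, 41), end = c(50, 73)), 100)
  expect_equal(cs$coverage, 73)
  expect_equal(cs$redundancy, 83 / 73, tolerance = 1e-12)
  expect_equal(coverageStats(data.frame(start = numeric(),
                                        end = numeric()), 100)$coverage, 0)
  expect_error(coverageStats(data.frame(start = 90, end = 120), 100),
               "bounds")
  # permutation invariance and oracle agreement on random maps
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    st <- sample(1:90, n, replace = TRUE)
    peps <- data.frame(start = st, end = pmin(st + sample(5:20, n, TRUE), 100))
    a <- coverageStats(peps, 100)
    b <- coverageStats(peps[sample(n), ], 100)
    o <- oracleCoverage(peps, 100)
    expect_equal(a$coverage, b$coverage)
    expect_equal(a$coverage, o$coverage)
    expect_equal(a$redundancy, o$redundancy)
  }
})

test_that("residue projection aggregates covering peptides", {
  d1 <- data.frame(start = 11, end = 20, dRFU = 0.3)
  tr <- projectToResidues(d1, seqLength = 25)
  expect_true(all(tr[11:20] == 0.3))
  expect_true(all(is.na(tr[c(1:10, 21:25)])))
  d2 <- data.frame(start = c(1, 6), end = c(10, 15), dRFU = c(0.1, 0.3))
  tr2 <- projectToResidues(d2)
  expect_equal(tr2[6:10], rep(0.2, 5))
  # nested peptides in min_length mode: overlap takes the shorter value
  d3 <- data.frame(start = c(1, 4), end = c(20, 8), dRFU = c(0.5, -0.2))
  tr3 <- projectToResidues(d3, mode = "min_length")
  expect_equal(tr3[4:8], rep(-0.2, 5))
  expect_equal(tr3[1:3], rep(0.5, 3))
})

test_that("residue tracks are written into PDB B-factors", {
  # synthetic three-residue helix fragment, constructed in code
  pdb <- tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      12.560   8.040  -4.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3      14.000  10.000  -2.000  1.00  0.00           C",
    "END")
  writeLines(lines, pdb)
  out <- tempfile(fileext = ".pdb")
  writeResidueTrackPDB(pdb, c(0.123, NA, 150), out)
  back <- bio3d::read.pdb(out)
  expect_equal(back$atom$b, c(0.12, 0, 99.99))
  expect_equal(back$atom$o, c(1, 0, 1))
})
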