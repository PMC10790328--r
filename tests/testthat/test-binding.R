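test_that("equilibrium solve matches the closed-form single-site cases", {
  # no depletion: x1 = 0.5 at L = K_D
  eq <- solveEquilibrium(bindingModel(1), ptot = 1e-9, ltot = 1)
  expect_equal(unname(eq$fractions["x1"]), 0.5, tolerance = 1e-6)
  # with depletion the free ligand is the quadratic root of
  # L^2 - 14 L - 20 = 0: L = 7 + sqrt(69)
  eq <- solveEquilibrium(bindingModel(1), ptot = 5, ltot = 20)
  Lref <- 7 + sqrt(69)
  expect_equal(eq$freeL, Lref, tolerance = 1e-8)
  expect_equal(unname(eq$fractions["x1"]), Lref / (1 + Lref),
               tolerance = 1e-8)
  # no ligand
  eq0 <- solveEquilibrium(bindingModel(c(1, 2)), ptot = 5, ltot = 0)
  expect_identical(unname(eq0$fractions), c(1, 0, 0))
  expect_identical(eq0$freeL, 0)
})

test_that("solver agrees with an independent bisection oracle", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(1:4, 1)
    kd <- 10^runif(n, -2, 2)
    ptot <- 10^runif(1, -1, 1.5)
    ltot <- 10^runif(1, -2, 2.5)
    eq <- solveEquilibrium(bindingModel(kd), ptot, ltot)
    expect_lt(abs(eq$freeL - oracleFreeL(kd, ptot, ltot)),
              1e-8 * max(1, ltot))
  }
})

test_that("equilibrium outputs conserve mass and normalize", {
  set.seed(12)
  for (i in 1:50) {
    kd <- 10^runif(4, -1, 2)
    ptot <- runif(1, 1, 10); ltot <- runif(1, 0, 100)
    eq <- solveEquilibrium(bindingModel(kd), ptot, ltot)
    x <- eq$fractions
    expect_equal(sum(x), 1, tolerance = 1e-9)
    bound <- ptot * sum(seq_len(4) * x[-1])
    expect_lt(abs(eq$freeL + bound - ltot), 1e-6 * max(1, ltot))
  }
})

test_that("bound fraction is monotone in totals and in the constants", {
  des <- titrationDesign(5, c(0, 1, 2, 5, 10, 20, 50), 1L)
  mod <- bindingModel(c(2, 4, 8, 16))
  tab <- predictTitration(mod, des)
  expect_true(all(diff(tab$x0) < 0))         # x0 strictly decreasing
  bound <- 1 - tab$x0
  expect_true(all(diff(bound) > 0))
  # non-increasing in every K_Di; asserted in the no-depletion limit
  # (with depletion, weakening a late site frees ligand that can raise
  # occupancy of the first site)
  desND <- titrationDesign(1e-9, des@ltot, 1L)
  boundND <- 1 - predictTitration(mod, desND)$x0
  for (i in 1:4) {
    kd2 <- kdValues(mod); kd2[i] <- kd2[i] * 3
    tab2 <- predictTitration(bindingModel(kd2), desND)
    expect_true(all(1 - tab2$x0 <= boundND + 1e-12))
  }
})

test_that("titration at zero lipid is all-apo for any model", {
  for (n in 1:4) {
    tab <- predictTitration(bindingModel(seq_len(n)),
                            titrationDesign(5, c(0, 1), 1L))
    expect_equal(unname(unlist(tab[1, -1])), c(1, rep(0, n)))
  }
})

test_that("noiseless single-site data are refit essentially exactly", {
  des <- titrationDesign(5, c(0, 0.25, 0.5, 1, 2, 4, 8, 16), 1L)
  tab <- predictTitration(bindingModel(2), des)
  tab$replicate <- 1L
  fit <- fitKds(tab, nSites = 1, design = des)
  expect_equal(kdValues(fit)[1], 2, tolerance = 1e-3)
  expect_gt(fit@r2, 0.9999)
})

test_that("noisy preset titrations are recovered with high R2", {
  pre <- titrationPreset("fl-pip2")
  errs <- vapply(1:5, function(s) {
    d <- genTitration(pre, seed = s, cv = 0.05)
    f <- fitKds(d, nSites = 4, design = pre@design)
    expect_gt(f@r2, 0.95)
    abs(log(kdValues(f)[1] / 0.7))
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("jackknife SDs are zero for identical replicates, positive for noisy", {
  pre <- titrationPreset("fl-pi")
  d0 <- genTitration(pre, seed = 1, cv = 0)
  f0 <- fitKds(d0, nSites = 4, design = pre@design)
  expect_true(all(f0@sd < 1e-6))
  d1 <- genTitration(pre, seed = 1, cv = 0.05)
  f1 <- fitKds(d1, nSites = 4, design = pre@design)
  expect_true(all(f1@sd > 0))
})

test_that("fit errors on underdetermined designs", {
  des <- titrationDesign(5, c(0, 1, 2), 1L)
  tab <- predictTitration(bindingModel(c(1, 2)), des)
  expect_error(fitKds(tab, nSites = 2, design = des), "at least")
})

test_that("model-order selection recovers the generating order", {
  des1 <- titrationDesign(5, c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32), 1L)
  tab1 <- predictTitration(bindingModel(2), des1)
  sel1 <- selectNSites(tab1, des1, maxSites = 3L)
  expect_identical(sel1$nSites, 1L)
  pre <- titrationPreset("fl-pi")
  tab4 <- genTitration(pre, seed = 2, cv = 0)
  sel4 <- selectNSites(tab4, pre@design, maxSites = 4L)
  expect_identical(sel4$nSites, 4L)
  expect_false(sel4$noBinding)
})

test_that("flat apo-only data are flagged as no binding", {
  des <- titrationDesign(5, c(0, 1, 2, 5, 10, 20), 1L)
  flat <- data.frame(lipid_conc_uM = des@ltot, x0 = 1, x1 = 0)
  sel <- suppressMessages(suppressWarnings(
    selectNSites(flat, des, maxSites = 1L)))
  expect_true(sel$noBinding)
  expect_gt(kdValues(sel$fits[[1]])[1], 1e3)
})

test_that("paired construct presets give a >10-fold affinity ratio on refit", {
  kd1 <- vapply(c("fl-pip2", "trunc-pip2"), function(nm) {
    pre <- titrationPreset(nm)
    d <- genTitration(pre, seed = 1, cv = 0)
    kdValues(fitKds(d, nSites = 4, design = pre@design))[1]
  }, 0)
  expect_gt(kd1[["trunc-pip2"]] / kd1[["fl-pip2"]], 10)
})
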