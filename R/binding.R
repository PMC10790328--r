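# Sequential ligand-binding equilibria with ligand depletion, and fitting
# of stepwise dissociation constants to titration mole fractions.

#' Construct a sequential binding model
#'
#' @param kd numeric vector of stepwise dissociation constants
#'   K_D1..K_Dn in micromolar (1-4 sites), where
#'   K_Di = \[P.L_(i-1)\]\[L\]/\[P.L_i\] against *free* ligand.
#' @return a [BindingModel-class].
#' @examples
#' bindingModel(c(0.7, 2.1, 6.3, 18.9))
#' @export
bindingModel <- function(kd) {
  new("BindingModel", kd = as.numeric(kd))
}

#' Construct a titration design
#'
#' @param ptot total protein concentration in micromolar (default 5).
#' @param ltot strictly increasing grid of total lipid concentrations in
#'   micromolar.
#' @param replicates replicates per grid point (default 3).
#' @return a [TitrationDesign-class].
#' @export
titrationDesign <- function(ptot = 5, ltot, replicates = 3L) {
  new("TitrationDesign", ptot = as.numeric(ptot), ltot = as.numeric(ltot),
      replicates = as.integer(replicates))
}

# Mole fractions x_i = beta_i L^i / sum_j beta_j L^j at free ligand L,
# with beta_i = 1 / prod_{j<=i} K_Dj.
.fractionsAtFreeL <- function(kd, L) {
  logBeta <- c(0, -cumsum(log(kd)))
  logTerm <- logBeta + seq(0, length(kd)) * log(max(L, .Machine$double.xmin))
  if (L == 0) logTerm[-1] <- -Inf
  w <- exp(logTerm - max(logTerm))
  w / sum(w)
}

# Mass-balance residual f(L) = L + ptot * <i>(L) - ltot; strictly
# increasing in L on [0, ltot].
.massBalance <- function(L, kd, ptot, ltot) {
  x <- .fractionsAtFreeL(kd, L)
  L + ptot * sum(seq_along(kd) * x[-1]) - ltot
}

#' Solve the sequential-binding equilibrium at one titration point
#'
#' Finds the unique non-negative free-ligand concentration satisfying the
#' mass balance L_tot = \[L\] + P_tot * sum(i * x_i), then returns the
#' species mole fractions x_0..x_n. Solved by safeguarded root bracketing
#' to a relative tolerance of 1e-10; non-convergence is an error, never a
#' silent return.
#'
#' @param model a [BindingModel-class].
#' @param ptot,ltot total protein and lipid concentrations in micromolar.
#' @return list with `freeL` (micromolar) and `fractions` (named numeric
#'   x0..xn summing to 1).
#' @examples
#' solveEquilibrium(bindingModel(1), ptot = 5, ltot = 20)
#' @export
solveEquilibrium <- function(model, ptot, ltot) {
  stopifnot(is(model, "BindingModel"), ptot > 0, ltot >= 0)
  kd <- model@kd
  n <- length(kd)
  if (ltot == 0) {
    return(list(freeL = 0,
                fractions = stats::setNames(c(1, rep(0, n)),
                                            paste0("x", 0:n))))
  }
  tol <- 1e-10 * max(1, ltot)
  root <- tryCatch(
    stats::uniroot(.massBalance, interval = c(0, ltot), kd = kd,
                   ptot = ptot, ltot = ltot, tol = tol * 1e-3,
                   f.lower = -ltot, maxiter = 2000L),
    error = function(e) {
      stop(sprintf(paste0("equilibrium solver failed to converge ",
                          "(ptot=%g, ltot=%g, f(0)=%g, f(ltot)=%g): %s"),
                   ptot, ltot, .massBalance(0, kd, ptot, ltot),
                   .massBalance(ltot, kd, ptot, ltot), conditionMessage(e)))
    })
  L <- root$root
  x <- .fractionsAtFreeL(kd, L)
  bal <- abs(L + ptot * sum(seq_len(n) * x[-1]) - ltot)
  if (bal > 1e-6 * max(1, ltot))
    stop(sprintf("mass balance violated after solve: |resid| = %g at ltot = %g",
                 bal, ltot))
  list(freeL = L, fractions = stats::setNames(x, paste0("x", 0:n)))
}

#' Predict a mole-fraction titration curve
#'
#' One equilibrium solve per grid point of the design, emitted as a
#' mole-fraction table (columns `lipid_conc_uM`, `x0`..`xn`).
#'
#' @param model a [BindingModel-class].
#' @param design a [TitrationDesign-class].
#' @return data.frame with one row per grid point.
#' @export
predictTitration <- function(model, design) {
  stopifnot(is(design, "TitrationDesign"))
  rows <- lapply(design@ltot, function(lt) {
    eq <- solveEquilibrium(model, design@ptot, lt)
    c(lipid_conc_uM = lt, eq$fractions)
  })
  as.data.frame(do.call(rbind, rows))
}

# Residuals of a mole-fraction table against a model prediction.
.titrationResiduals <- function(logKd, data, ptot, speciesCols) {
  kd <- 10^logKd
  ltots <- sort(unique(data$lipid_conc_uM))
  pred <- vapply(ltots, function(lt) {
    .fractionsAtFreeL(kd, .solveFreeL(kd, ptot, lt))
  }, numeric(length(logKd) + 1))
  predRows <- t(pred)[match(data$lipid_conc_uM, ltots), , drop = FALSE]
  obs <- as.matrix(data[, speciesCols, drop = FALSE])
  k <- min(ncol(obs), ncol(predRows))
  as.vector(obs[, seq_len(k)] - predRows[, seq_len(k)])
}

# Scalar free-ligand solve without object overhead (fitter hot path).
.solveFreeL <- function(kd, ptot, ltot) {
  if (ltot == 0) return(0)
  stats::uniroot(.massBalance, interval = c(0, ltot), kd = kd, ptot = ptot,
                 ltot = ltot, tol = 1e-13 * max(1, ltot), f.lower = -ltot,
                 maxiter = 2000L)$root
}

.fitOnce <- function(start, data, ptot, speciesCols, bounds) {
  obj <- function(p) sum(.titrationResiduals(p, data, ptot, speciesCols)^2)
  fit <- stats::nlminb(start, obj, lower = bounds[1], upper = bounds[2],
                       control = list(iter.max = 500L, eval.max = 1000L))
  fit
}

#' Fit stepwise dissociation constants to titration mole fractions
#'
#' Least squares over all species curves and concentrations jointly, in
#' log10(K_D) space with box bounds \[1e-3, 1e4\] micromolar, using
#' multi-start local optimization (starts spanning 1e-2 to 1e3
#' micromolar). Ties among optima are broken by lowest SSE then lowest
#' K_D1. The pooled R2 is 1 - SSE/SST with SST about the grand mean over
#' all species curves; standard deviations are obtained by jackknifing
#' over replicates.
#'
#' @param data mole-fraction table: data.frame with `lipid_conc_uM`,
#'   optional `replicate`, and species columns `x0`, `x1`, ...
#' @param nSites number of sequential binding events to fit (1-4).
#' @param design a [TitrationDesign-class]; only `ptot` is consulted (the
#'   concentration grid is taken from `data`).
#' @param nStarts number of multi-start points (>= 8 recommended).
#' @return a [BindingFit-class].
#' @examples
#' mod <- bindingModel(2)
#' des <- titrationDesign(5, c(0, 0.5, 1, 2, 5, 10, 20), 1L)
#' tab <- predictTitration(mod, des)
#' fitKds(tab, nSites = 1, design = des)
#' @export
fitKds <- function(data, nSites, design, nStarts = 8L) {
  stopifnot(is.data.frame(data), nSites >= 1, nSites <= 4,
            is(design, "TitrationDesign"))
  if (!"lipid_conc_uM" %in% names(data))
    stop("data must have a lipid_conc_uM column")
  speciesCols <- grep("^x[0-9]+$", names(data), value = TRUE)
  if (!length(speciesCols)) stop("data must have species columns x0, x1, ...")
  speciesCols <- speciesCols[order(as.integer(sub("x", "", speciesCols)))]
  nConc <- length(unique(data$lipid_conc_uM))
  if (nConc < nSites + 2)
    stop(sprintf("need at least %d distinct concentrations to fit %d site(s), got %d",
                 nSites + 2, nSites, nConc))
  bounds <- c(-3, 4)  # log10 uM
  kd1Starts <- seq(-2, 3, length.out = nStarts)
  starts <- lapply(kd1Starts, function(k1)
    k1 + log10(3) * (seq_len(nSites) - 1))
  fits <- lapply(starts, .fitOnce, data = data, ptot = design@ptot,
                 speciesCols = speciesCols, bounds = bounds)
  sses <- vapply(fits, `[[`, 0, "objective")
  kd1s <- vapply(fits, function(f) f$par[1], 0)
  best <- order(sses, kd1s)[1]
  fit <- fits[[best]]
  kd <- 10^fit$par
  res <- .titrationResiduals(fit$par, data, design@ptot, speciesCols)
  useCols <- speciesCols[seq_len(min(length(speciesCols), nSites + 1))]
  obs <- as.vector(as.matrix(data[, useCols, drop = FALSE]))
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst > 0) 1 - fit$objective / sst else NA_real_
  atBound <- abs(fit$par - bounds[1]) < 1e-6 | abs(fit$par - bounds[2]) < 1e-6
  if (any(atBound))
    warning("fit hit optimizer bounds for K_D", paste(which(atBound),
            collapse = ", "))
  sds <- rep(NA_real_, nSites)
  if ("replicate" %in% names(data)) {
    reps <- unique(data$replicate)
    if (length(reps) >= 2) {
      jack <- vapply(reps, function(r) {
        sub <- data[data$replicate != r, , drop = FALSE]
        f <- .fitOnce(fit$par, sub, design@ptot, speciesCols, bounds)
        f$par
      }, numeric(nSites))
      jack <- matrix(jack, nrow = nSites)
      m <- length(reps)
      theta <- 10^jack
      sds <- sqrt((m - 1) / m * rowSums((theta - rowMeans(theta))^2))
    }
  }
  resDf <- data.frame(
    lipid_conc_uM = rep(data$lipid_conc_uM, length(useCols)),
    species = rep(useCols, each = nrow(data)),
    residual = res)
  new("BindingFit", kd = kd, sd = sds, r2 = r2, sse = fit$objective,
      converged = fit$convergence == 0, atBound = atBound,
      residuals = resDf, nStarts = as.integer(nStarts))
}

#' Choose the number of sequential binding events
#'
#' Fits 1..`maxSites` models and selects by the small-sample-corrected
#' Akaike criterion (AICc) on the pooled Gaussian residuals. A dataset
#' with no binding (flat x0 = 1) is flagged: all constants sit at the
#' upper optimizer bound.
#'
#' @param data mole-fraction table as for [fitKds()].
#' @param design a [TitrationDesign-class].
#' @param maxSites maximum number of events to consider (default 4).
#' @return list with `nSites` (chosen), `fits` (per-n [BindingFit-class]),
#'   `aicc` (per-n), `noBinding` (logical flag).
#' @export
selectNSites <- function(data, design, maxSites = 4L) {
  fits <- list()
  aicc <- rep(NA_real_, maxSites)
  for (n in seq_len(maxSites)) {
    fits[[n]] <- withCallingHandlers(
      fitKds(data, nSites = n, design = design),
      warning = function(w) invokeRestart("muffleWarning"))
    nObs <- nrow(fits[[n]]@residuals)
    k <- n
    sse <- max(fits[[n]]@sse, .Machine$double.xmin)
    aicc[n] <- nObs * log(sse / nObs) + 2 * k +
      2 * k * (k + 1) / max(nObs - k - 1, 1)
  }
  nBest <- which.min(aicc)
  noBinding <- all(fits[[nBest]]@atBound) && fits[[nBest]]@kd[1] > 1e3
  if (noBinding)
    message("no binding detected: all K_D estimates at the upper bound")
  list(nSites = nBest, fits = fits, aicc = aicc, noBinding = noBinding)
}
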