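# Seeded synthetic-data generators: titration tables, native-MS peak
# lists and four-state HDX uptake tables, with named presets emulating
# the study conditions every analysis stage is verified against.

# Printed first dissociation constants (uM) behind the titration presets;
# higher-order constants follow a 2x ladder, the weakest geometric decay
# under which all four binding events of the PI preset stay above a 2%
# detection threshold at 20 uM lipid, as observed.
.PRESET_KD1 <- c("fl-pip2" = 0.7, "trunc-pip2" = 9.9, "fl-pi" = 6,
                 "fl-pi4p" = 6, "fl-pip3" = 6, "fl-pe" = 120)

# 12-point total-lipid grids (uM): 0-50 for the high-affinity presets,
# extended to bracket the weak PE constant.
.GRID_50 <- c(0, 0.5, 1, 2, 3, 5, 7.5, 10, 15, 20, 30, 50)
.GRID_600 <- c(0, 5, 10, 20, 40, 60, 100, 150, 200, 300, 450, 600)

#' Named synthetic titration presets
#'
#' Each preset bundles a ground-truth four-event sequential binding model
#' (K_D1 from the printed constants: 0.7 uM full-length PI(4,5)P2, 9.9 uM
#' truncated PI(4,5)P2, ~6 uM PI / PI(4)P / PIP3, 20-fold weaker PE;
#' K_D(i+1) = 2 K_Di above that), a titration design (P_tot 5 uM, 12
#' concentrations, n = 3), and a default multiplicative intensity noise.
#'
#' @param name one of `"fl-pip2"`, `"trunc-pip2"`, `"fl-pi"`, `"fl-pi4p"`,
#'   `"fl-pip3"`, `"fl-pe"`.
#' @param cv multiplicative Gaussian noise CV applied to intensities
#'   before renormalization (default 0.05).
#' @param ltot optional replacement concentration grid (uM).
#' @param replicates replicates per point (default 3).
#' @return a [TitrationPreset-class].
#' @examples
#' titrationPreset("fl-pip2")
#' @export
titrationPreset <- function(name, cv = 0.05, ltot = NULL, replicates = 3L) {
  if (!name %in% names(.PRESET_KD1))
    stop("unknown titration preset: ", name, "; available: ",
         paste(names(.PRESET_KD1), collapse = ", "))
  kd1 <- .PRESET_KD1[[name]]
  kd <- kd1 * 2^(0:3)
  if (is.null(ltot)) ltot <- if (name == "fl-pe") .GRID_600 else .GRID_50
  new("TitrationPreset", name = name, model = bindingModel(kd),
      design = titrationDesign(5, ltot, replicates), cv = cv)
}

#' Generate a synthetic mole-fraction titration table
#'
#' Predicts the equilibrium mole fractions from the preset truth, applies
#' multiplicative Gaussian noise to the species intensities, truncates at
#' zero and renormalizes each row to sum to 1. The ground-truth model is
#' attached as attribute `"truth"` for recovery tests. Fully reproducible
#' from the seed.
#'
#' @param preset a [TitrationPreset-class].
#' @param seed integer RNG seed.
#' @param cv noise CV override; defaults to the preset value (use 0 for a
#'   noiseless table).
#' @return data.frame with columns `lipid_conc_uM`, `replicate`,
#'   `x0`..`x4`, plus attribute `truth` (the generating
#'   [BindingModel-class]).
#' @export
genTitration <- function(preset, seed = 1L, cv = preset@cv) {
  stopifnot(is(preset, "TitrationPreset"))
  pred <- predictTitration(preset@model, preset@design)
  spc <- grep("^x", names(pred), value = TRUE)
  reps <- preset@design@replicates
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rows <- list()
  for (r in seq_len(reps)) {
    tab <- pred
    if (cv > 0) {
      noise <- matrix(stats::rnorm(nrow(tab) * length(spc), 1, cv),
                      nrow(tab))
      x <- pmax(as.matrix(tab[spc]) * noise, 0)
      tab[spc] <- x / rowSums(x)
    }
    tab$replicate <- r
    rows[[r]] <- tab
  }
  out <- do.call(rbind, rows)
  out <- out[, c("lipid_conc_uM", "replicate", spc)]
  attr(out, "truth") <- preset@model
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Named synthetic native-MS spectrum presets
#'
#' `"fl"` and `"trunc"` emulate a single delipidated transporter (58.0 /
#' 48.2 kDa) titrated with PI(18:1/18:1); `"mixture"` emulates the
#' equimolar two-protein experiment with the substrate lysolipid S1P
#' bound at one site per protein.
#'
#' @param name `"fl"`, `"trunc"` or `"mixture"`.
#' @param fractions list of per-protein bound-state fraction vectors
#'   (x0..xk); defaults: the fl-pi preset equilibrium at 20 uM lipid for
#'   the single-protein presets, and single-site occupancies at 5-fold
#'   different K_D for the mixture.
#' @param sigmaTh Gaussian peak sigma in Thomson (default 2).
#' @param noiseFloor additive noise SD relative to a base peak of 100
#'   (default 0.3).
#' @return a [SpectrumPreset-class].
#' @export
spectrumPreset <- function(name, fractions = NULL, sigmaTh = 2,
                           noiseFloor = 0.3) {
  cfg <- switch(name,
    fl = list(masses = c(fl = 58000), zc = 17, zw = 1.6,
              zr = c(13L, 21L), lipid = "PI(18:1/18:1)"),
    trunc = list(masses = c(trunc = 48200), zc = 14, zw = 1.4,
                 zr = c(11L, 18L), lipid = "PI(18:1/18:1)"),
    mixture = list(masses = c(fl = 58000, trunc = 48200), zc = c(17, 14),
                   zw = c(1.6, 1.4), zr = c(11L, 21L), lipid = "S1P"),
    stop("unknown spectrum preset: ", name))
  if (is.null(fractions)) {
    fractions <- if (name == "mixture") {
      # single-site occupancy at fixed free ligand 2 uM, K_D 2 vs 10 uM
      list(fl = c(1, 2 / 2) / sum(c(1, 2 / 2)),
           trunc = c(1, 2 / 10) / sum(c(1, 2 / 10)))
    } else {
      eq <- solveEquilibrium(titrationPreset("fl-pi")@model, 5, 20)
      list(unname(eq$fractions))
    }
  }
  new("SpectrumPreset", name = name, masses = cfg$masses,
      zCenter = rep_len(cfg$zc, length(cfg$masses)),
      zWidth = rep_len(cfg$zw, length(cfg$masses)),
      zRange = as.integer(cfg$zr), lipid = cfg$lipid,
      fractions = fractions, sigmaTh = sigmaTh, noiseFloor = noiseFloor,
      mzStep = 0.1)
}

#' Generate a synthetic native-MS profile spectrum
#'
#' Gaussian peaks at m/z = (M + k * m_lipid + z * 1.00728)/z for every
#' protein, charge state and bound stoichiometry, with intensities given
#' by the charge envelope times the state fraction, plus an additive
#' noise floor. Every emitted peak is traceable to a (protein, z, k)
#' tuple in the returned inventory.
#'
#' @param preset a [SpectrumPreset-class].
#' @param seed integer RNG seed (noise floor only).
#' @param threshold relative intensity below which a (z, k) combination
#'   is omitted from both spectrum and inventory (default 1e-3 of the
#'   base peak).
#' @return list with `profile` (a [PeakList-class]) and `inventory`
#'   (data.frame: protein, z, k, mz, intensity).
#' @export
genSpectrum <- function(preset, seed = 1L, threshold = 1e-3) {
  stopifnot(is(preset, "SpectrumPreset"))
  mLip <- lipidMass(preset@lipid)
  mp <- .PROTON_MASS
  inv <- list()
  for (p in seq_along(preset@masses)) {
    fr <- preset@fractions[[min(p, length(preset@fractions))]]
    zs <- seq(preset@zRange[1], preset@zRange[2])
    env <- exp(-((zs - preset@zCenter[p])^2) / (2 * preset@zWidth[p]^2))
    for (j in seq_along(zs)) for (k in seq_along(fr) - 1L) {
      int <- 100 * env[j] * fr[k + 1]
      if (int < 100 * threshold) next
      M <- preset@masses[p] + k * mLip
      inv[[length(inv) + 1]] <- data.frame(
        protein = names(preset@masses)[p] %||% as.character(p),
        z = zs[j], k = k, mz = (M + zs[j] * mp) / zs[j], intensity = int)
    }
  }
  inventory <- do.call(rbind, inv)
  lo <- min(inventory$mz) - 8 * preset@sigmaTh
  hi <- max(inventory$mz) + 8 * preset@sigmaTh
  grid <- seq(lo, hi, by = preset@mzStep)
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(inventory)))
    y <- y + inventory$intensity[i] *
      exp(-((grid - inventory$mz[i])^2) / (2 * preset@sigmaTh^2))
  if (preset@noiseFloor > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    y <- pmax(y + abs(stats::rnorm(length(y), 0, preset@noiseFloor)), 0)
  }
  list(profile = peakList(grid, y, label = preset@name),
       inventory = inventory)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- HDX stand-in transporter -------------------------------------------

# Deterministic 549-residue stand-in sequence (no RNG): a repeating
# membrane-protein-like alphabet with sparse prolines every 47 residues.
.standinSequence <- function(n = 549L) {
  pool <- strsplit("LAGVFISTMWYNQEDKRHC", "")[[1]]
  aa <- pool[((seq_len(n) * 7L) %% length(pool)) + 1L]
  aa[seq_len(n) %% 47L == 0L] <- "P"
  paste(aa, collapse = "")
}

# MFS-like topology of the stand-in: 12 TMs (split into extracellular and
# cytoplasmic halves where state effects differ by side), loops, the two
# intracellular helices, and the termini. Covers residues 1..549 once.
.standinTopology <- function() {
  t <- rbind(
    c("Nterm", 1, 104, "term"),
    c("TM1_cyt", 105, 114, "TM"), c("TM1_ext", 115, 128, "TM"),
    c("L1-2", 129, 142, "loop"),
    c("TM2_ext", 143, 154, "TM"), c("TM2_cyt", 155, 166, "TM"),
    c("L2-3", 167, 178, "loop"),
    c("TM3", 179, 200, "TM"), c("L3-4", 201, 206, "loop"),
    c("TM4", 207, 226, "TM"), c("L4-5", 227, 234, "loop"),
    c("TM5", 235, 249, "TM"), c("L5-6", 250, 255, "loop"),
    c("TM6_ext", 256, 266, "TM"), c("TM6_cyt", 267, 278, "TM"),
    c("ICH1", 279, 292, "ICH"), c("ICH2", 293, 305, "ICH"),
    c("TM7_cyt", 306, 328, "TM"), c("TM7_ext", 329, 342, "TM"),
    c("L7-8", 343, 348, "loop"),
    c("TM8", 349, 372, "TM"), c("L8-9", 373, 380, "loop"),
    c("TM9", 381, 404, "TM"), c("L9-10", 405, 412, "loop"),
    c("TM10", 413, 436, "TM"), c("L10-11", 437, 448, "loop"),
    c("TM11_cyt", 449, 462, "TM"), c("TM11_ext", 463, 478, "TM"),
    c("L11-12", 479, 486, "loop"),
    c("TM12_ext", 487, 498, "TM"), c("TM12_cyt", 499, 512, "TM"),
    c("Cterm", 513, 549, "term"))
  data.frame(region = t[, 1], start = as.integer(t[, 2]),
             end = as.integer(t[, 3]), class = t[, 4])
}

# Two-phase exchange kinetics per structural class (1/min): a fast
# sub-minute population and a slow hours-scale population, scaled so apo
# RFU at 60 min is ~0.49 in TMs and ~0.85-0.93 in loops/termini.
.standinKinetics <- function() {
  data.frame(class = c("TM", "loop", "ICH", "term"),
             fFast = c(0.35, 0.60, 0.50, 0.60),
             kFast = c(1.5, 3, 2, 3),
             kSlow = c(0.004, 0.03, 0.02, 0.03))
}

# Per-state rate multipliers: substrate binding protects TM8 rapidly and
# deprotects the extracellular gate slowly; the signaling phosphoinositide
# protects the N terminus and the cytoplasmic face rapidly and deprotects
# the extracellular ends of TM1/TM2/TM7/TM11 slowly.
.standinEffects <- function() {
  e <- rbind(
    data.frame(state = "S1P", region = "TM8", fastMult = 0.05, slowMult = 1),
    data.frame(state = "S1P",
               region = c("TM1_ext", "L1-2", "TM2_ext", "TM7_ext"),
               fastMult = 1, slowMult = 2.0),
    data.frame(state = "PIP2",
               region = c("Nterm", "TM1_cyt", "TM2_cyt", "L2-3", "L4-5",
                          "ICH1", "TM8", "L10-11", "ICH2"),
               fastMult = 0.1, slowMult = 1),
    data.frame(state = "PIP2",
               region = c("TM1_ext", "TM2_ext", "TM7_ext", "TM11_ext"),
               fastMult = 1, slowMult = 1.8))
  e
}

.GATE_REGIONS <- c("TM1_ext", "TM2_ext", "TM6_ext", "TM7_ext", "TM11_ext",
                   "TM12_ext")

#' Named synthetic four-state HDX presets
#'
#' The stand-in transporter (549 residues, 12 TMs, two intracellular
#' helices) is exchanged under four states (`apo`, `S1P`, `PIP2`,
#' `ternary`) over the 1/60/180/360 min exposure grid. Presets:
#' `"synergy"` (default study emulation) makes the ternary slow-phase
#' rate boost at the extracellular gate twice the additive single-ligand
#' increment; `"additive"` constructs the ternary uptake exactly
#' RFU-additive in expectation (synergy null); `"null"` removes all state
#' effects (every state exchanges like apo).
#'
#' @param name `"synergy"`, `"additive"` or `"null"`.
#' @param noiseSd replicate noise SD in Da (default 0.15).
#' @return an [HDXPreset-class].
#' @export
hdxPreset <- function(name = c("synergy", "additive", "null"),
                      noiseSd = 0.15) {
  name <- match.arg(name)
  eff <- .standinEffects()
  if (name == "null") eff <- eff[0, ]
  new("HDXPreset", name = name, sequence = .standinSequence(),
      topology = .standinTopology(), kinetics = .standinKinetics(),
      effects = eff, gateRegions = .GATE_REGIONS,
      synergyFactor = if (name == "synergy") 2 else 1,
      ternaryMode = if (name == "additive") "additive" else "synergistic",
      noiseSd = noiseSd)
}

# Per-residue region and class lookup vectors.
.residueRegions <- function(topology, n) {
  reg <- character(n); cls <- character(n)
  for (i in seq_len(nrow(topology))) {
    idx <- topology$start[i]:topology$end[i]
    reg[idx] <- topology$region[i]
    cls[idx] <- topology$class[i]
  }
  list(region = reg, class = cls)
}

# Exchanged fraction of residue r at time t for a given state, using the
# two-phase model u = f*(1-exp(-kf*mf*t)) + (1-f)*(1-exp(-ks*ms*t)).
.residueUptakeFraction <- function(preset, t, state) {
  n <- nchar(preset@sequence)
  look <- .residueRegions(preset@topology, n)
  kin <- preset@kinetics
  ki <- match(look$class, kin$class)
  fF <- kin$fFast[ki]; kF <- kin$kFast[ki]; kS <- kin$kSlow[ki]
  mF <- rep(1, n); mS <- rep(1, n)
  if (state %in% c("S1P", "PIP2")) {
    eff <- preset@effects[preset@effects$state == state, , drop = FALSE]
    for (j in seq_len(nrow(eff))) {
      idx <- look$region == eff$region[j]
      mF[idx] <- mF[idx] * eff$fastMult[j]
      mS[idx] <- mS[idx] * eff$slowMult[j]
    }
  } else if (state == "ternary") {
    uA <- .residueUptakeFraction(preset, t, "apo")
    uS <- .residueUptakeFraction(preset, t, "S1P")
    uP <- .residueUptakeFraction(preset, t, "PIP2")
    u <- pmin(pmax(uS + uP - uA, 0), 1)   # additive in expectation
    if (preset@ternaryMode == "synergistic") {
      # at the gate the slow-phase boost is synergyFactor times the
      # additive rate increment (with a floor opening the gate even where
      # single ligands are silent)
      gate <- look$region %in% preset@gateRegions
      effAll <- preset@effects
      addBoost <- rep(0, n)
      for (st in c("S1P", "PIP2")) {
        eff <- effAll[effAll$state == st, , drop = FALSE]
        for (j in seq_len(nrow(eff))) {
          idx <- look$region == eff$region[j]
          addBoost[idx] <- addBoost[idx] + (eff$slowMult[j] - 1)
        }
      }
      mSg <- pmax(1 + preset@synergyFactor * addBoost, 2)
      uGate <- fF * (1 - exp(-kF * t)) +
        (1 - fF) * (1 - exp(-kS * mSg * t))
      # the cytoplasmic protection of the phosphoinositide persists in
      # the ternary state; at the gate there is no fast-phase effect
      u[gate] <- uGate[gate]
    }
    return(u)
  }
  fF * (1 - exp(-kF * mF * t)) + (1 - fF) * (1 - exp(-kS * mS * t))
}

#' Tile peptides over a sequence
#'
#' Deterministic-given-seed tiling with lengths 8-16 and start offset 5,
#' the granularity of a typical pepsin map.
#'
#' @param seqLength protein length.
#' @param seed integer RNG seed (peptide lengths).
#' @param lengths candidate peptide lengths (default 8:16).
#' @param offset start-to-start offset (default 5).
#' @return data.frame with columns `start`, `end`.
#' @export
tilePeptides <- function(seqLength, seed = 1L, lengths = 8:16, offset = 5L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  starts <- seq(1L, seqLength - min(lengths), by = offset)
  len <- sample(lengths, length(starts), replace = TRUE)
  end <- pmin(starts + len - 1L, seqLength)
  data.frame(start = starts, end = end)
}

# Marker peptides pinned into every generated map so that region-level
# readouts can be addressed at exact coordinates.
.MARKER_PEPTIDES <- data.frame(
  start = c(28, 115, 117, 127, 143, 158, 259, 335, 336, 470),
  end   = c(34, 120, 126, 142, 147, 164, 263, 340, 340, 478))

#' Generate a synthetic four-state HDX uptake table
#'
#' Peptides are tiled over the stand-in sequence (plus fixed marker
#' peptides at the study's readout coordinates), and uptake
#' D(t) = sum over exchange-competent amides of the residue exchanged
#' fraction is evaluated for each state and exposure, with Gaussian
#' replicate noise truncated to \[0, N_max\].
#'
#' @param preset an [HDXPreset-class].
#' @param seed integer RNG seed (tiling and noise).
#' @param replicates replicates per state/exposure (default 3).
#' @param exposures exposure grid in minutes (default c(1, 60, 180, 360)).
#' @param peptides optional data.frame (`start`, `end`) replacing the
#'   default tiling.
#' @param states states to emit (default all four).
#' @return an [HDXDataset-class]; the noiseless expected uptake is
#'   attached as attribute `"truth"` (data.frame start, end, state,
#'   exposure, uptake).
#' @export
genHdx <- function(preset, seed = 1L, replicates = 3L,
                   exposures = c(1, 60, 180, 360), peptides = NULL,
                   states = c("apo", "S1P", "PIP2", "ternary")) {
  stopifnot(is(preset, "HDXPreset"))
  n <- nchar(preset@sequence)
  if (is.null(peptides)) {
    peptides <- rbind(tilePeptides(n, seed = seed), .MARKER_PEPTIDES)
    peptides <- unique(peptides)
    peptides <- peptides[order(peptides$start, peptides$end), ]
  }
  aa <- strsplit(preset@sequence, "")[[1]]
  pepSeq <- vapply(seq_len(nrow(peptides)), function(i)
    paste(aa[peptides$start[i]:peptides$end[i]], collapse = ""), "")
  nmax <- maxUptake(pepSeq)
  # residues contributing amides: positions 2..len, excluding prolines
  amideIdx <- lapply(seq_len(nrow(peptides)), function(i) {
    r <- (peptides$start[i] + 1L):peptides$end[i]
    r[aa[r] != "P"]
  })
  truth <- list(); rows <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) + 1L)
  for (st in states) for (ex in exposures) {
    u <- .residueUptakeFraction(preset, ex, st)
    D <- vapply(amideIdx, function(idx) sum(u[idx]), 0)
    truth[[length(truth) + 1]] <- data.frame(
      start = peptides$start, end = peptides$end, state = st,
      exposure = ex, uptake = D)
    for (r in seq_len(replicates)) {
      obs <- if (preset@noiseSd > 0)
        pmin(pmax(D + stats::rnorm(length(D), 0, preset@noiseSd), 0), nmax)
      else D
      rows[[length(rows) + 1]] <- data.frame(
        start = peptides$start, end = peptides$end, sequence = pepSeq,
        state = st, exposure = ex, replicate = r, uptake = obs)
    }
  }
  ds <- hdxDataset(do.call(rbind, rows), exposures = exposures)
  attr(ds, "truth") <- do.call(rbind, truth)
  ds
}

#' Topology annotation of the stand-in transporter
#'
#' @return data.frame with columns `region`, `start`, `end`, `class`.
#' @export
transporterTopology <- function() .standinTopology()

#' Sequence of the stand-in transporter
#'
#' A deterministic 549-residue synthetic sequence; it is a stand-in, not
#' a database sequence.
#'
#' @return character(1).
#' @export
transporterSequence <- function() .standinSequence()
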