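#' @import methods
NULL

#' PeakList: an ordered native-MS peak list
#'
#' Container for a native mass-spectrometry peak list, either a raw profile
#' trace or picked centroids. m/z values are stored strictly increasing and
#' intensities are non-negative.
#'
#' @slot mz numeric, m/z in Thomson, strictly increasing.
#' @slot intensity numeric, intensities in arbitrary units, >= 0.
#' @slot metadata list with optional `label` and `replicate` entries.
#'
#' @seealso [peakList()], [pickPeaks()], [deconvolveMass()]
#' @export
setClass("PeakList",
  representation(mz = "numeric", intensity = "numeric", metadata = "list"),
  prototype(mz = numeric(), intensity = numeric(), metadata = list())
)

setValidity("PeakList", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (anyNA(object@mz) || anyNA(object@intensity))
    msg <- c(msg, "mz/intensity must not contain NA")
  if (length(object@mz) > 1 && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly increasing")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ChargeSeries: one deconvolved charge-series assignment
#'
#' A single neutral mass explaining a set of peaks at consecutive (possibly
#' gapped) positive charge states, with per-state mass residuals.
#'
#' @slot mass numeric(1), neutral mass in Da.
#' @slot charges integer, matched charge states (positive).
#' @slot peakIndex integer, indices into the source PeakList, parallel to
#'   `charges`.
#' @slot residuals numeric, neutral-mass residuals (observed - expected) in
#'   Da, parallel to `charges`.
#' @slot score numeric(1), intensity-weighted match score used for ranking.
#' @export
setClass("ChargeSeries",
  representation(mass = "numeric", charges = "integer",
                 peakIndex = "integer", residuals = "numeric",
                 score = "numeric")
)

setValidity("ChargeSeries", function(object) {
  msg <- character()
  if (length(object@mass) != 1 || object@mass <= 0)
    msg <- c(msg, "mass must be a single positive number")
  if (any(object@charges < 1))
    msg <- c(msg, "charges must be positive integers")
  n <- length(object@charges)
  if (length(object@peakIndex) != n || length(object@residuals) != n)
    msg <- c(msg, "charges, peakIndex and residuals must be parallel")
  if (length(msg)) msg else TRUE
})

#' AdductAssignment: lipid-adduct stoichiometry assignment of a spectrum
#'
#' Result of matching peaks above a base (apo) charge series to ladders
#' M0 + k * lipid mass for one or more candidate lipids.
#'
#' @slot baseMass numeric(1), apo neutral mass M0 in Da.
#' @slot assignments data.frame with columns `charge`, `peakIndex`, `lipid`
#'   (NA for the apo species), `k` (stoichiometry, 0 for apo), `mz`,
#'   `intensity`, `residual` (Da, neutral space), `ambiguous` (logical).
#' @slot maxStoichiometry integer(1), the configured ladder maximum.
#' @export
setClass("AdductAssignment",
  representation(baseMass = "numeric", assignments = "data.frame",
                 maxStoichiometry = "integer")
)

setValidity("AdductAssignment", function(object) {
  need <- c("charge", "peakIndex", "lipid", "k", "mz", "intensity",
            "residual", "ambiguous")
  if (!all(need %in% names(object@assignments)))
    return(paste("assignments must have columns:", paste(need, collapse = ", ")))
  if (any(object@assignments$k < 0)) return("stoichiometries must be >= 0")
  if (any(object@assignments$k > object@maxStoichiometry))
    return("stoichiometry exceeds configured maximum")
  TRUE
})

#' BindingModel: sequential ligand-binding equilibria
#'
#' Stepwise dissociation constants K_Di = [P.L_{i-1}][L]/[P.L_i] for up to
#' four sequential, non-cooperative lipid binding events.
#'
#' @slot kd numeric vector of stepwise dissociation constants in micromolar,
#'   ordered K_D1..K_Dn; all > 0; length 1-4.
#' @seealso [bindingModel()], [solveEquilibrium()], [fitKds()]
#' @export
setClass("BindingModel", representation(kd = "numeric"))

setValidity("BindingModel", function(object) {
  if (length(object@kd) < 1 || length(object@kd) > 4)
    return("between 1 and 4 binding events are supported")
  if (anyNA(object@kd) || any(object@kd <= 0))
    return("all K_D values must be positive")
  TRUE
})

#' TitrationDesign: protein and lipid totals of a titration
#'
#' @slot ptot numeric(1), total protein concentration in micromolar
#'   (default 5, the concentration used in a typical native-MS titration).
#' @slot ltot numeric, strictly increasing grid of total lipid
#'   concentrations in micromolar, >= 0.
#' @slot replicates integer(1), replicates per grid point.
#' @export
setClass("TitrationDesign",
  representation(ptot = "numeric", ltot = "numeric", replicates = "integer")
)

setValidity("TitrationDesign", function(object) {
  msg <- character()
  if (length(object@ptot) != 1 || object@ptot <= 0)
    msg <- c(msg, "ptot must be a single positive concentration")
  if (any(object@ltot < 0)) msg <- c(msg, "ltot must be >= 0")
  if (length(object@ltot) > 1 && any(diff(object@ltot) <= 0))
    msg <- c(msg, "ltot grid must be strictly increasing")
  if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' BindingFit: fitted sequential dissociation constants
#'
#' @slot kd numeric, estimated K_D1..K_Dn in micromolar.
#' @slot sd numeric, jackknife standard deviations (NA when < 2 replicates).
#' @slot r2 numeric(1), pooled coefficient of determination across all
#'   species curves.
#' @slot sse numeric(1), residual sum of squares at the optimum.
#' @slot converged logical(1), optimizer convergence of the best start.
#' @slot atBound logical, per-parameter flag for estimates at the box bounds.
#' @slot residuals data.frame of per-point residuals (ltot, species,
#'   observed, fitted).
#' @slot nStarts integer(1), number of multi-start optimizations run.
#' @export
setClass("BindingFit",
  representation(kd = "numeric", sd = "numeric", r2 = "numeric",
                 sse = "numeric", converged = "logical",
                 atBound = "logical", residuals = "data.frame",
                 nStarts = "integer")
)

setValidity("BindingFit", function(object) {
  msg <- character()
  if (length(object@r2) != 1 || object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2 must be a single value <= 1")
  if (any(!is.na(object@sd) & object@sd < 0))
    msg <- c(msg, "sd must be >= 0")
  if (length(object@atBound) != length(object@kd))
    msg <- c(msg, "atBound must be parallel to kd")
  if (length(msg)) msg else TRUE
})

#' HDXDataset: peptide-level deuterium uptake measurements
#'
#' Long-format uptake table (one row per peptide x state x exposure x
#' replicate) together with a derived peptide table carrying the
#' theoretical maximum uptake N_max for each peptide.
#'
#' @slot uptake data.frame with columns `start`, `end`, `sequence`, `state`,
#'   `exposure` (minutes), `replicate`, `uptake` (Da).
#' @slot peptides data.frame with columns `start`, `end`, `sequence`,
#'   `nmax` (exchange-competent amides).
#' @slot exposures numeric, the configured exposure grid in minutes.
#' @seealso [hdxDataset()], [computeRfu()], [deltaRfu()], [synergy()]
#' @export
setClass("HDXDataset",
  representation(uptake = "data.frame", peptides = "data.frame",
                 exposures = "numeric")
)

setValidity("HDXDataset", function(object) {
  need <- c("start", "end", "sequence", "state", "exposure", "replicate",
            "uptake")
  if (!all(need %in% names(object@uptake)))
    return(paste("uptake must have columns:", paste(need, collapse = ", ")))
  if (any(object@uptake$uptake < 0, na.rm = TRUE))
    return("uptake values must be >= 0")
  if (!all(object@uptake$exposure %in% object@exposures))
    return("all exposures must lie on the configured exposure grid")
  if (!all(c("start", "end", "sequence", "nmax") %in% names(object@peptides)))
    return("peptides must have columns start, end, sequence, nmax")
  TRUE
})

#' TitrationPreset: a named synthetic titration scenario
#'
#' Bundles a ground-truth [BindingModel-class], a [TitrationDesign-class]
#' and a multiplicative intensity noise level, reproducible from a seed.
#'
#' @slot name character(1) preset name.
#' @slot model BindingModel ground truth.
#' @slot design TitrationDesign.
#' @slot cv numeric(1), coefficient of variation of the multiplicative
#'   Gaussian intensity noise applied before renormalization.
#' @seealso [titrationPreset()], [genTitration()]
#' @export
setClass("TitrationPreset",
  representation(name = "character", model = "BindingModel",
                 design = "TitrationDesign", cv = "numeric")
)

setValidity("TitrationPreset", function(object) {
  if (object@cv < 0) return("cv must be >= 0")
  TRUE
})

#' SpectrumPreset: a synthetic native-MS spectrum scenario
#'
#' @slot name character(1).
#' @slot masses named numeric, neutral protein mass(es) in Da.
#' @slot zCenter numeric, charge-envelope center per protein.
#' @slot zWidth numeric, Gaussian envelope width (charge units) per protein.
#' @slot zRange integer(2), charge states emitted.
#' @slot lipid character(1), bound lipid name from [lipidTable()].
#' @slot fractions list of per-protein bound-state fraction vectors
#'   (x_0..x_k); alternatively filled from a binding model by the caller.
#' @slot sigmaTh numeric(1), Gaussian peak sigma in Thomson (resolution
#'   model).
#' @slot noiseFloor numeric(1), additive noise SD relative to a base peak of
#'   100.
#' @slot mzStep numeric(1), profile grid step in Thomson.
#' @seealso [spectrumPreset()], [genSpectrum()]
#' @export
setClass("SpectrumPreset",
  representation(name = "character", masses = "numeric", zCenter = "numeric",
                 zWidth = "numeric", zRange = "integer", lipid = "character",
                 fractions = "list", sigmaTh = "numeric",
                 noiseFloor = "numeric", mzStep = "numeric")
)

#' HDXPreset: a synthetic four-state HDX scenario
#'
#' Carries the stand-in transporter sequence, its topology annotation,
#' per-class two-phase exchange parameters and per-state, per-region rate
#' multipliers.
#'
#' @slot name character(1).
#' @slot sequence character(1), the protein sequence.
#' @slot topology data.frame (region, start, end, class) covering every
#'   residue once.
#' @slot kinetics data.frame per structural class: `class`, `fFast`
#'   (fraction of fast-exchanging amides), `kFast`, `kSlow` (1/min).
#' @slot effects data.frame of state perturbations: `state`, `region`,
#'   `fastMult`, `slowMult`.
#' @slot gateRegions character, regions with super-additive gate opening in
#'   the ternary state.
#' @slot synergyFactor numeric(1), ternary slow-rate boost relative to the
#'   additive single-ligand rate increments (1 = additive in rate).
#' @slot ternaryMode character(1), "synergistic" or "additive" (ternary
#'   uptake constructed exactly RFU-additive in expectation).
#' @slot noiseSd numeric(1), replicate noise SD in Da.
#' @seealso [hdxPreset()], [genHdx()]
#' @export
setClass("HDXPreset",
  representation(name = "character", sequence = "character",
                 topology = "data.frame", kinetics = "data.frame",
                 effects = "data.frame", gateRegions = "character",
                 synergyFactor = "numeric", ternaryMode = "character",
                 noiseSd = "numeric")
)

setValidity("HDXPreset", function(object) {
  if (!object@ternaryMode %in% c("synergistic", "additive"))
    return("ternaryMode must be 'synergistic' or 'additive'")
  top <- object@topology
  covered <- unlist(Map(seq.int, top$start, top$end))
  if (anyDuplicated(covered) || length(covered) != nchar(object@sequence))
    return("topology must cover every residue exactly once")
  TRUE
})
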