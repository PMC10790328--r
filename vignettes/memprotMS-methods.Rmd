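---
title: "Models and methods in memprotMS"
author: "memprotMS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in memprotMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprotMS)
```

memprotMS quantifies two complementary views of lipid regulation of a
membrane transporter: *how much* lipid binds (native MS titrations and
the sequential binding model) and *what the binding does* (time-resolved
HDX-MS differential and synergy analysis). This vignette documents the
models, their assumptions, the tunable parameters, the synthetic-data
generator, and the numerical and design choices made where the design
was genuinely open.

## The sequential ligand-binding model

Lipid binding to the transporter P is modeled as up to four sequential,
thermodynamically independent events

$$\mathrm{P{\cdot}L_{i-1} + L \rightleftharpoons P{\cdot}L_i},\qquad
K_{Di} = \frac{[\mathrm{P{\cdot}L_{i-1}}][\mathrm{L}]}{[\mathrm{P{\cdot}L_i}]},$$

so the mole fraction of the i-lipid-bound species at free lipid
concentration $[\mathrm{L}]$ is

$$x_i = \frac{[\mathrm{L}]^i / \prod_{j\le i} K_{Dj}}
             {\sum_k [\mathrm{L}]^k / \prod_{j\le k} K_{Dj}}.$$

**Depletion.** The constants are defined against *free*, not total,
lipid. At the working protein concentration (P_tot = 5 μM) the
highest-affinity constants (sub-micromolar) are far below P_tot, so the
no-depletion approximation would bias fits badly. `solveEquilibrium()`
therefore finds $[\mathrm{L}]$ as the unique non-negative root of

$$L_{tot} = [\mathrm{L}] + P_{tot}\sum_i i\,x_i([\mathrm{L}]),$$

a strictly increasing scalar function bracketed on
$[0, L_{tot}]$, solved by safeguarded root finding to a relative
tolerance of 1e-10. Non-convergence is an error with bracketing
diagnostics, never a silent return. The species weights are accumulated
in log space so extreme constant/concentration combinations cannot
overflow.

Detergent partitioning of lipid is ignored (total aqueous lipid is
treated as available); the mole-fraction readout itself assumes equal
ionization efficiency of apo and bound species. Both assumptions are
inherited from the standard native-MS titration protocol.

One caveat worth recording: total bound fraction is *not* globally
non-increasing in every $K_{Di}$ once depletion is active — weakening a
late binding event frees ligand that can raise first-site occupancy at
fixed $L_{tot}$. The monotonicity property is asserted (and holds) in
the no-depletion limit.

**Fitting.** `fitKds()` minimizes the summed squared residuals over all
species curves and concentrations jointly, in $\log_{10} K_D$ space with
box bounds $[10^{-3}, 10^4]$ μM. The objective has local optima (a
permutation-like ambiguity between neighboring constants when the data
barely constrain higher events), so 8 multi-starts span $10^{-2}$ to
$10^3$ μM; ties are broken by lowest SSE then lowest K_D1. $R^2$ is the
single pooled statistic $1 - SSE/SST$ with SST about the grand mean of
all species values, matching the convention of one printed $R^2$ per
titration panel. Uncertainties are leave-one-replicate-out jackknife
SDs; with a single (or noiseless) replicate set they are zero/NA by
construction. The exact weighting and error model of historical
processing scripts is not published, so unweighted least squares with
jackknife SDs is this package's own, documented choice.

`selectNSites()` compares n = 1..4 by AICc on the pooled Gaussian
residuals; a flat titration drives all constants to the upper bound and
is flagged "no binding" rather than reported as a fit.

## Native-MS peak processing

* `pickPeaks()` estimates the noise floor as median + `minSnr`·MAD of
  the trace, keeps local maxima above it, enforces a minimum centroid
  spacing (default 5 Th; apexes closer than that merge), and centroids
  by intensity-weighted mean after subtracting the baseline median —
  without the subtraction the noise floor inside the window biases
  centroids by tenths of a Thomson, which at charge 17 is several Da.
* `deconvolveMass()` scans every (peak, charge) candidate neutral mass
  under the positive-ion convention m/z = (M + z·1.00728)/z, scores by
  intensity-weighted matched-charge count, and refines by a trimmed
  intensity-weighted mean: centroids distorted by overlapping satellite
  peaks (e.g. a high-stoichiometry adduct of one charge state landing
  on the apo peak of another) are trimmed at 3·MAD before the final
  mass estimate. Candidates explaining < 3 charge states are rejected.
  Average (not monoisotopic) masses are used throughout: at ~58 kDa and
  instrument resolving power in the 10^4 range isotopes are unresolved.
* `assignLipidAdducts()` matches neutralized peaks to
  $M_0 + k\,m_{lipid}$ ladders with a ±3 Da tolerance in neutral-mass
  space — unambiguous against the ~80 Da phosphate-ladder spacing —
  flagging, not resolving, peaks that two candidate lipids could
  explain. Stoichiometries are capped at 4.
* `moleFractions()` normalizes by the total intensity of all observed
  species, summed across charge states by default; a `per_charge` mode
  reproduces single-charge-state readouts. A bound stoichiometry is
  counted as a detected binding event when its mole fraction reaches
  0.02.

Lipid masses come from `lipidTable()`: formulas are constructed from
head group and acyl composition ("Cx:y/Cx:y" parsed, never guessed) as
free acids — the observed ~863 Da adduct spacing matches the free-acid
mass of di-18:1 phosphatidylinositol, and whether observed adducts are
protonated or deprotonated is not determinable from the data, so the
free-acid convention is a decision, not a measurement. Phosphoinositide
masses are built by adding HPO3 units to the PI formula, making the
ladder spacing exact by construction. Atomic weights (IUPAC standard,
4 decimals) are baked in for reproducibility.

## HDX-MS analysis

RFU is measured uptake over the theoretical maximum
N_max = length − 1 − (prolines after the first residue); the first amide
is treated as fully back-exchanged, the convention of commercial HDX
processing software. No back-exchange correction is applied — RFU is
relative throughout.

ΔRFU compares a ligand state with apo per peptide and exposure using a
two-tailed unpaired Welch t-test at α = 0.05, with no multiplicity
correction by default (per-peptide stars are the field's reporting
convention; Benjamini-Hochberg is available via `adjust = "BH"`). The
synergy statistic $S = \Delta RFU_{ternary} - (\Delta RFU_{S1P} +
\Delta RFU_{PIP2})$ shares the apo mean across its three differences, so
its variance is propagated as $\sum_g s_g^2/n_g$ over the four state
groups with a Welch–Satterthwaite df; a one-sided p for $S > 0$ is
reported alongside the two-sided p.

Residue projection averages the covering peptides by default; the
`min_length` mode takes the shortest covering peptide for sharper
localization. Projections are written to PDB B-factors clamped to
[−9.99, 99.99] with missing residues at 0.00/occupancy 0 (fixed-width
format limits). Coordinates are 1-based inclusive everywhere.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes — it is the package's verification instrument, not a physics
simulator.

**Titrations** (`titrationPreset()`, `genTitration()`). The preset
truths take the printed first dissociation constants: 0.7 μM
(full-length, PI(4,5)P2), 9.9 μM (truncated, PI(4,5)P2), ~6 μM (PI,
PI(4)P, PIP3), and 20-fold weaker than PI for PE (120 μM). Only first
constants are printed anywhere, so higher-order constants follow a
geometric ladder $K_{D(i+1)} = 2K_{Di}$. The factor 2 is the weakest
geometric decay under which all four PI binding events stay above the
2% detection threshold at 20 μM lipid — the observed behavior — while
keeping higher-order occupancy decreasing; a factor 3 pushes the fourth
event below detectability at that concentration. Designs use P_tot
5 μM, 12 concentrations (0–50 μM; extended to 600 μM for PE so the grid
brackets the constant), n = 3. Noise is multiplicative Gaussian on
intensities (CV 0.05 by default) before renormalization.

**Spectra** (`spectrumPreset()`, `genSpectrum()`). Gaussian peaks
(σ = 2 Th, a realistic width for an intact 58 kDa membrane protein on
an Orbitrap-class instrument) at every (protein, z, k) position, with a
Gaussian charge envelope (center 17 for the 58.0 kDa full-length
protein, 14 for the 48.2 kDa truncation) and an additive noise floor.
The masses are round stand-ins, not database values. The mixture preset
fixes free substrate at 2 μM with single-site K_Ds of 2 and 10 μM — a
5-fold affinity difference with apo peaks dominant, the regime of the
two-protein competition experiment; no constants are printed for that
experiment, so these are generator choices. Every peak is traceable to
the emitted inventory.

**HDX** (`hdxPreset()`, `genHdx()`). The stand-in transporter is a
deterministic 549-residue synthetic sequence with an MFS-like topology
(12 TMs split into extracellular/cytoplasmic halves, two intracellular
helices, termini). Exchange is two-phase per structural class: a fast
sub-minute amide population and a slow hours-scale population
($u = f(1-e^{-k_f t}) + (1-f)(1-e^{-k_s t})$). A single-exponential
segment model cannot show both sub-minute protection effects and late
deprotection, which the data clearly require. Rates are scaled so apo
RFU at 60 min is ~0.49 in TMs and ~0.85–0.93 in loops/termini, the
qualitative protection pattern of an MFS fold. State effects are rate
multipliers per region: substrate binding suppresses the fast phase at
TM8 (×0.05, the rapid lateral-entry protection) and doubles the slow
phase at the extracellular gate (TM1/L1-2/TM2/TM7 ends); the
phosphoinositide suppresses the fast phase (×0.1) at the N terminus and
the cytoplasmic face while raising the slow phase (×1.8) at the
extracellular ends of TM1/TM2/TM7/TM11. The ternary state is
constructed RFU-additive in expectation everywhere except the gate,
where the slow-phase rate increment is twice the additive sum (with a
floor that opens TM6/TM12 even though neither single ligand affects
them) — the super-additive signature. The `additive` preset removes the
boost (exact synergy null below saturation; at the longest exposure the
[0, 1] RFU clip makes strict additivity impossible, so null checks read
the 60 min slice), and `null` removes all effects. Replicate noise is
Gaussian with SD 0.15 Da truncated to [0, N_max], n = 3.

What the generator does *not* emulate: back-exchange, intrinsic-rate
sequence dependence (Bai–Englander chemistry), EX1 bimodality,
ionization physics, detergent effects, peptide misidentification.
Passing tests therefore demonstrate the correctness of the statistical
machinery under the stated model, not robustness to every artifact of
real data.

## Numerical choices and degenerate inputs

* Equilibrium solves: relative tolerance 1e-10; mass balance re-checked
  to 1e-6·max(1, L_tot) after the solve; L_tot = 0 short-circuits to
  the all-apo state.
* Fits: log-space bounds [1e-3, 1e4] μM; estimates within 1e-6 of a
  bound are flagged; fewer distinct concentrations than n+2 is an
  error.
* t-tests: zero within-group variance in both groups is degenerate —
  the test is skipped with a warning (NA p), except that two literally
  identical replicate sets report p = 1 (no difference, by
  construction).
* RFU: cells with n = 1 are an error, n = 2 a warning; peptides with
  N_max = 0 (lone/flanking prolines) are dropped with a message.
* Peak picking: an all-zero trace returns an empty peak list, not an
  error.

## Problem sizes

The test and acceptance workloads are desk-scale by design: 1,000
random equilibrium instances against the bisection oracle, ~110
peptides × 4 states × 4 exposures × 3 replicates per HDX dataset
(~1,200 null tests for the type-I calibration), 12-concentration
titrations, and single-protein spectra of a few dozen peaks. The full
suite runs in about a minute on one CPU.

## Known limitations

* The sequential model is non-cooperative by construction; Hill/Adair
  alternatives are out of scope.
* Printed "±" uncertainties in the literature may be replicate-fit SDs
  or fit standard errors; the jackknife here is one defensible choice,
  not a reproduction of an unpublished pipeline.
* Raw instrument files (mzML, DynamX exports with richer metadata) are
  not parsed; peak lists and state-data CSVs are the ingestion points.
* Whether titration mole fractions should be computed on one charge
  state or summed across all is not standardized; both modes are
  provided (`summed` is the default, matching normalization by total
  observed intensity).
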