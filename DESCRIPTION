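Package: memprotMS
Title: Native Mass Spectrometry Lipid Binding and HDX-MS Conformational
    Analysis for Membrane Transporters
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of protein-lipid interactions of membrane
    transporters measured by native mass spectrometry and hydrogen-deuterium
    exchange mass spectrometry (HDX-MS). Provides charge-series deconvolution
    of native MS peak lists, lipid-adduct assignment against a built-in
    phospholipid mass table, bound-state mole fractions, a sequential
    ligand-binding equilibrium model with ligand depletion and per-event
    dissociation-constant fitting, competition and mixture analyses,
    time-resolved HDX-MS differential uptake (delta-RFU) and two-ligand
    synergy statistics with residue-level projection, and seeded synthetic
    data generators that emulate titrations, spectra and four-state uptake
    tables for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, bio3d, Biostrings
Suggests: testthat (>= 3.0.0), jsonlite, optparse
biocViews: MassSpectrometry, Proteomics, Lipidomics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
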