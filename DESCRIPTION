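Package: dboxr
Title: Detection and Biophysical Characterization of Beta-Strand Recruitment
    Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying beta-strand recruitment of short peptide
    motifs by periplasmic protein domains, motivated by the TonB/ExbD system
    of Gram-negative bacteria. Implements hydropathy-pattern scanning for the
    D-box motif (a hydrophobic/hydrophilic heptad flanked by prolines) with a
    Chou-Fasman-style beta-strand propensity gate; single-site binding
    isotherm models and fits for isothermal titration calorimetry and
    fluorescence anisotropy titrations, including an exact ligand-depletion
    quadratic; structural analyses of recruitment complexes (Kabsch
    superposition, Shrake-Rupley solvent-accessible surface area and burial
    fractions, Kabsch-Sander backbone hydrogen bonds, parallel/antiparallel
    beta-bridge typing, sheet topology); pairwise conservation analysis with
    Clustal-style column classes mapped onto structures; and seeded synthetic
    data generators for every input class so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
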