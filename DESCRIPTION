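Package: nfyscreen
Title: Pocket-Targeted Evolutionary Docking and Assay Analytics for
    NF-Y Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in silico discovery workflow for small-molecule
    inhibitors of the NF-Y transcription factor and the quantitative
    analytics used to characterize hits.  Provides PDB structure
    handling and search-box definition around a pocket residue,
    rigid-conformer elitist genetic-algorithm docking with an
    empirical Lennard-Jones/Coulomb/clash scoring function,
    post-screen triage (cLogP window, PAINS-style SMARTS flags,
    Tanimoto max-min diversity selection), molecular-dynamics
    trajectory readouts (ligand RMSD, per-residue RMSF, contact
    occupancy, per-frame interaction-enthalpy series), dose-response
    IC50 and cycloheximide-chase half-life estimation, and seeded
    synthetic-data generators with presets for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
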