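Package: quenchbind
Title: Fluorescence-Quenching Analysis of Ligand-Protein Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterizing small-molecule binding to proteins from
    fluorescence-quenching titrations and companion experiments: Stern-Volmer
    and double-logarithmic binding fits, quenching-mechanism classification
    (static vs. dynamic), Van't Hoff thermodynamics with dominant-force
    labelling, multi-exponential TCSPC lifetime tail fitting, synchronous-scan
    shift analysis, excitation-emission-matrix peak picking with Rayleigh
    scatter masking, enzyme-activity assay arithmetic, and post-simulation
    trajectory observables (Kabsch-superposed RMSD, RMSF, radius of gyration,
    ligand-residue distances, geometric hydrogen-bond counts). A synthetic-data
    module generates every input class with known ground truth so the whole
    pipeline is testable without instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
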