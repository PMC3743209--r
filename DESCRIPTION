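Package: transelect
Title: Ligand- and Structure-Based Selectivity Analysis for Monoamine
    Transporter Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probing substrate selectivity of the serotonin and
    dopamine transporters (SERT/DAT). Combines a ligand-based layer --
    selectivity indices and matched-pair comparisons on a phenylethylamine
    activity table, and binding free energy differences from affinity
    ratios -- with a structure-based post-docking layer: salt-bridge
    (ionic interaction) pose filtering against the conserved aspartate,
    symmetry-aware common-scaffold RMSD clustering with complete linkage,
    consensus pose selection from the top-ranked lists of two scoring
    functions with cluster-average rescoring, and a binding-pocket residue
    comparison with hydropathy contrasts. Includes a synthetic pose-ensemble
    generator with planted binding modes, contacts and score structure so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    bio3d,
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    jsonlite
Config/testthat/edition: 3
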