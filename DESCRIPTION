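Package: allodyn
Title: Allosteric Pathway Analysis of Protein Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis stack for studying allosteric communication in protein
    complexes from molecular-dynamics-style trajectories: Kabsch superposition
    with RMSD/RMSF fluctuation statistics, dynamic cross-correlation matrices
    (DCCM) and essential-dynamics PCA, correlation-weighted residue interaction
    networks with optimal and bounded suboptimal path enumeration, geometric
    detection of interface hydrogen bonds, salt bridges and cation-pi contacts,
    and MM/GBSA end-state free-energy bookkeeping with per-residue
    decomposition. Includes a synthetic-trajectory generator that plants known
    correlation structure, interface geometries and toy energy systems so every
    stage is testable against analytic ground truth; shipped reference tables
    for the H-Ras-NS1-GDP complex (wild type vs R135K) drive the worked
    wild-type-versus-mutant comparison workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
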