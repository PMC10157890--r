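Package: kdacselect
Title: Substrate-Selectivity Mapping for Lysine Deacetylases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the substrate-selectivity surfaces of
    metal-dependent lysine deacetylases (KDACs/HDACs) from molecular-dynamics
    trajectories of enzyme-acetylpeptide complexes and peptide activity
    panels. Detects per-frame van der Waals contacts, hydrogen bonds and
    ionic interactions between enzyme residues and substrate positions,
    aggregates them into replicate-averaged percent-time frequency tables
    with catalytic-pose and low-frequency exclusion, and associates
    interactions with deacetylation activity through substrate-cluster
    t-tests (Bonferroni), Mann-Whitney activity tests, frame co-occurrence
    Fisher tests and Pearson correlations. Also provides endpoint-activity
    normalization, pairwise significance matrices, Michaelis-Menten kinetics
    fitting with catalytic efficiency, Fisher's-exact residue-presence
    validation, and seeded generators of synthetic trajectories, activity
    panels and kinetic timecourses so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
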