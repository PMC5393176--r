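Package: rnassess
Title: Quality Assessment of RNA Three-Dimensional Structure Models
Version: 0.1.0
Authors@R:
    person("RNA", "Assessment Toolkit Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Compares predicted RNA three-dimensional models against one or
    more reference crystal structures with the metric panel used in blind
    RNA structure prediction assessment: optimal-superposition RMSD,
    interaction network fidelity (INF) split into Watson-Crick, non
    Watson-Crick and stacking contributions, deformation index (DI), the
    per-nucleotide deformation profile (DP) with domain-level aggregation,
    the mean of circular quantities (MCQ) in torsion-angle space, and a
    steric clash score. Includes PDB and mmCIF readers, geometric base-pair
    and stacking annotation with Leontis-Westhof edge classification,
    model ranking and radar-rank report data, B-factor profiles, and a
    deterministic generator of idealized A-form RNA structures with
    controlled perturbations for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
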