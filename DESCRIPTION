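Package: ptggdyn
Title: Conformational Ensemble Analysis of Platinum-GG DNA Adducts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing conformational ensembles of platinated
    DNA duplexes: multi-model PDB input/output and duplex topology
    inference, intra-base-pair and base-pair-step helical parameters via
    a mid-frame (CEHS-style) decomposition built on the standard
    reference base geometries, geometric hydrogen-bond detection and
    per-frame classification of platinum-amine contacts, ensemble
    comparison statistics (Z-score and two-sample Kolmogorov-Smirnov
    heat-map matrices, class-conditional histograms), Kabsch
    superposition with iterative mean structures, family RMSD and
    centroid extraction, and a synthetic duplex-ensemble generator with
    controlled helical-parameter distributions and planted
    hydrogen-bond class fractions for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
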