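Package: subtract
Title: Protocol-Constrained Probabilistic Tractography and Connectivity
    Blueprints for Cortico-Subcortical Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for standardised cortico-subcortical
    tractography analyses. Provides probabilistic streamline tracking on
    multi-fibre orientation fields under seed/target/stop/exclusion protocol
    semantics, construction of grey-matter-by-tracts connectivity blueprints
    for cortex and subcortex, symmetric Kullback-Leibler divergence matching
    of connectivity patterns across species, tract-similarity and
    group-comparison statistics (thresholded Pearson correlations, exact
    Mann-Whitney U tests with Bonferroni correction), and anterograde-tracer
    termination-probability maps. A phantom module generates synthetic fibre
    fields with straight, curved and crossing bundles, matched two-species
    blueprints, and family-structured cohorts with known ground truth, so
    every analysis is testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
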