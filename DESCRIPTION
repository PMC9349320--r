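Package: mmclone
Title: Spatio-Temporal Clonal Evolution Analysis of Multiple Myeloma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing the spatial and temporal clonal
    evolution of multiple myeloma from multi-region, multi-timepoint
    whole-exome sequencing. Computes per-mutation cancer clonal fractions
    from read counts, tumor purity and local copy number; classifies
    paired-sample heterogeneity (shared, shared-differential, unshared);
    clusters mutations into subclones with a binomial mixture model and
    arranges them into clone trees; detects clonal sweeps and parallel
    evolution; fits 96-context mutational-signature exposures and tests
    for the presence of a treatment (melphalan-like) signature to flag
    single-cell expansions; classifies per-patient evolutionary patterns;
    and provides clinical association statistics (Fisher's exact test,
    Mann-Whitney, GEP70 risk score). A synthetic-cohort simulator with
    ground-truth labels makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
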