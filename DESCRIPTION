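Package: qprob
Title: Single-Model Protein Quality Assessment by Feature Error Probability Densities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the global quality (GDT-TS) of a single protein
    structural model without its native structure. Eleven structural,
    physicochemical and knowledge-based energy features are each treated as a
    noisy estimator of GDT-TS; per-feature error distributions fitted on a
    training set define Gaussian densities that are peak-normalized, weighted
    and summed into a combined probability score whose maximizer over [0,1]
    is the predicted quality. Includes length-dependent normalization of raw
    statistical-potential scores, coordinate-descent weight training against
    per-target GDT-TS loss, CASP-style evaluation metrics (per-target
    correlations, GDT-TS loss, Wilcoxon tests, Z-score sums), an internal
    Shrake-Rupley solvent-accessibility and dihedral-window secondary
    structure assigner with a DSSP-output reader, a GDT-TS implementation,
    and synthetic fixture generators so every stage runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
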