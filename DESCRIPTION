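Package: targetmr
Title: Drug-Target Mendelian Randomization, PheWAS and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for drug-target Mendelian randomization with GWAS
    summary statistics: harmonization of exposure and outcome association
    tables with proxy substitution, cis instrument selection with LD
    clumping, Wald-ratio and inverse-variance-weighted causal estimation
    (fixed, multiplicative random effects, and generalized least squares
    for correlated instruments), linear-to-odds-ratio conversion for
    binary traits analysed by linear regression, enumeration-based
    Bayesian colocalization with Wakefield approximate Bayes factors,
    phenome-wide association scans with Benjamini-Hochberg false
    discovery rate control, and a synthetic summary-statistics generator
    with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
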