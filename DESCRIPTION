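Package: metareduce
Title: Remove a Cohort's Contribution from Inverse-Variance-Weighted GWAS Meta-Analysis Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adjusts published fixed-effect inverse-variance-weighted (IVW)
    GWAS meta-analysis summary statistics to remove the contribution of one
    participating cohort in closed form, using only the meta-level (B, SE) and
    the cohort-level (beta, se) per-marker estimates. The adjusted statistics
    are algebraically equivalent to re-running the meta-analysis with that
    cohort excluded, which avoids sample-overlap inflation when the cohort is
    reused as a polygenic-score training or target set. Includes a fixed-effect
    IVW meta-analysis engine (the brute-force leave-one-out oracle), summary
    statistics readers and writers for configurable column dialects, allele
    harmonization, a seeded multi-cohort summary-statistics simulator, and a
    validation harness comparing the adjustment against leave-one-out
    recomputation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor
Config/testthat/edition: 3
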