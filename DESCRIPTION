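Package: kinseg
Title: Co-Segregation Bayes Factors and Pairwise IBD Segment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating rare-variant pathogenicity from family data.
    Computes the full-likelihood Bayes factor (FLB) for co-segregation of a
    variant with disease in pedigrees under an autosomal dominant model, with
    sex- and age-specific penetrance classes built from carrier and population
    cancer incidence tables (including penalized Poisson-spline pre-smoothing)
    and a penetrance sensitivity analysis with iso-FLB contours. Detects
    pairwise identity-by-descent (IBD) segments from two-sample genotype data
    with an identity-by-state sliding-window statistic, estimates the number
    of generations to a shared common ancestor from IBD segment length, and
    performs breakpoint coordinate arithmetic with HGVS-style annotation for
    duplication-insertion structural variants. Includes seeded generators for
    synthetic pedigrees, incidence tables and paired genotype data with
    planted IBD segments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mgcv,
    vcfR,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
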