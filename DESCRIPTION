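Package: hapqtl
Title: Haplotype-Based eQTL Mapping and Allelic-Series Estimation in
    Multiparental Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping expression quantitative trait loci (eQTL) in
    two-panel multiparental recombinant inbred line (RIL) crosses by regression
    on founder haplotype probabilities, and for quantifying allelic
    heterogeneity at mapped QTL.  Includes a synthetic-panel generator
    emulating an eight-founder advanced intercross resource, probe-level
    microarray quality control (SNP-in-probe filtering, median-polish
    summarization, principal-component batch correction), genome scans with
    permutation-based experiment-wise thresholds, peak calling with LOD-drop
    and Bayesian credible intervals, estimation of the number of functional
    alleles per QTL by exhaustive ordered-partition model comparison,
    trans-eQTL hotspot detection with a Poisson sliding-window test, and a
    simulation study evaluating the allele-number estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
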