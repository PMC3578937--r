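Package: sweepvalley
Title: Selective Sweep Detection and Demographic Calibration for
    Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-depth analysis of candidate selective-sweep regions
    from population samples of aligned haplotypes with an outgroup. Implements
    classical diversity statistics (Watterson's theta, pi, Tajima's D) in
    sliding windows, outgroup polarization and fixed-difference analysis, a
    composite-likelihood-ratio sweep scan against a simulation-estimated
    neutral site-frequency spectrum that includes invariant sites, the
    linkage-disequilibrium omega statistic with joint window-size and
    split-point maximization, a Hudson-style coalescent simulator with
    recombination under a three-population out-of-Africa bottleneck model,
    significance calibration of scan maxima from neutral replicates, and
    rejection approximate Bayesian computation for demographic parameters
    using monomorphic-fragment counts as additional summaries. Synthetic-data
    generators emulate genome-scan fragment panels and contiguous regions with
    an outgroup and an optional injected sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
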