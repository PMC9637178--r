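Package: petloops
Title: Chromatin Loop Calling and Regulatory Interaction Analysis from
    Paired-End Tags
Version: 0.1.0
Authors@R:
    person("petloops", "developers", email = "petloops@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for proximity-ligation-free chromatin
    interaction assays that report spatial contacts between accessible
    regions as intra-chromosomal paired-end tags (PETs). Covers
    pre-processing of raw read pairs (linker trimming, length and
    near-diagonal filters, PCR de-duplication, QC), density-based loop
    calling on PET 2D coordinates with local-permutation Poisson
    significance, aggregate (APA-style) loop enrichment, differential
    loop testing between conditions with MA-plot background calibration,
    transcription-factor loop-anchor co-binding enrichment with
    permutation FDR, virtual 4C profiles, montage interaction densities,
    promoter/enhancer annotation, CTCF motif orientation classes,
    enhancer-promoter network statistics, and a synthetic PET generator
    with ground-truth tables so the whole stack is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
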