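Package: pcovms
Title: Marker Ion Correlations by Two-Dimensional Partial Covariance
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identification of cofragmented combinatorial peptide isomers
    (for example variably acetylated histone tails) from fragment-fragment
    correlations in ensembles of tandem-MS microscans.  Provides exhaustive
    backbone fragment enumeration for modified peptides, in silico digestion
    and combinatorial isomer enumeration, discovery of isomer-unique marker
    ions and marker ion correlations, the total-ion-current partial
    covariance map estimator with jackknife-resampled peak significance
    scores, matching of scored correlation peaks to theoretical markers with
    relative quantification, and a synthetic microscan simulator with known
    correlation structure for validating the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
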