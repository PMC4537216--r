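Package: decurve
Title: Piecewise Time-Course Profile Fitting, Classification and
    mRNA-Protein Regulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits expression time courses (RNA-seq and spectral-count
    proteomics) with a seven-parameter piecewise continuous curve using a
    population-based differential-evolution optimizer whose cost is scaled
    by replicate error, classifies the fitted profiles into behavioral
    categories (up, down, transiently up, transiently down) with
    ensemble-agreement confidence, and compares protein dynamics against
    transcript dynamics under the two limiting models of proportional and
    integral regulation.  Includes count preprocessing (low-count and
    fold-change filters, depth and median-of-ratios normalization), operon
    co-expression coherence statistics, k-means profile clustering, RNA
    class fraction accounting, gene-set enrichment, a synthetic-data
    generator with known ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    deSolve,
    DESeq2
Config/testthat/edition: 3
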