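Package: cghdiv
Title: Estimating Gene-by-Gene Sequence Divergence from Array CGH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating genomic sequence divergence between a
    platform species and heterologous species from two-color array
    comparative genomic hybridization (aCGH). Provides quality filtering,
    minimum background correction and conserved-set loess normalization of
    two-channel scans; per-feature moderated t-tests with empirical Bayes
    variance shrinkage and Benjamini-Hochberg false discovery control to
    call features with significantly reduced heterologous hybridization;
    calibration of the log2 hybridization ratio against percent sequence
    identity (moving-window detection curves, logistic ID-50 detection
    limits, linear and hybridization-kinetics regressions); partitioning of
    technical versus hybridization-kinetics variance via a robust residual
    scale; replication power analysis over array subsets; parsing of BLAST
    tabular output into per-feature percent identity; Gene Ontology
    hypergeometric representation tests with ancestor propagation; and a
    synthetic two-color aCGH data generator with planted truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
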