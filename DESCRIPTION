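Package: polyseg
Title: Bulked-Segregant Mapping, Subgenome Expression Bias and Splicing
    Response Analysis for Triplicated Brassica Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the downstream analysis layer of a
    Brassica genome/transcriptome study. Implements bulked-segregant
    delta-(SNP-index) trait mapping with sliding windows and Monte-Carlo
    confidence envelopes, CDS-aware variant-effect annotation, classification
    of whole-genome-triplication triads into seven expression-bias categories
    on the ternary simplex, Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
    correction, transposable-element flank/body context and homolog expression
    contrasts, and PSI-based differential alternative splicing, differential
    transcript usage and nonsense-mediated-decay prediction. Every stage is
    exercisable end-to-end on built-in synthetic data generators that emulate
    the statistical structure each method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
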