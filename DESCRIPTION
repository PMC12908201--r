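Package: softclipr
Title: Soft-Clip Classification of Transgene-Derived RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates endogenous from exogenous (lentiviral-construct-derived)
    transcript reads in aligned RNA-seq data by classifying fragments that
    overlap the start of a gene's open reading frame according to their CIGAR
    soft-clip signature. Reads crossing the junction between an artificial
    5' tag and the coding sequence acquire soft-clipped bases when aligned to
    the reference genome, while reads from the native locus align contiguously
    through the 5'UTR. Includes a ground-truth simulator of aligned reads with
    known origin, evaluation helpers, and small downstream utilities for
    differential-expression threshold filtering, per-timepoint DEG set
    decomposition, and RT-qPCR relative expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stringr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
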