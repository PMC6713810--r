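Package: crypticlnc
Title: Annotation and Decay-Class Analysis of Cryptic Antisense lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates cryptic long noncoding RNAs from strand-specific
    RNA-seq coverage of RNA-decay-pathway mutants and classifies them by
    decay class (SUT, CUT, XUT, DUT). Implements sliding-window log2
    coverage segmentation with exhaustive parameter-grid exploration,
    spike-in and ORF-total size-factor normalization, a two-group
    negative-binomial Wald test with moderated dispersion for
    mutant-versus-wild-type stabilization calls, antisense/solo
    partitioning with sense-antisense overlap statistics, small-RNA
    (siRNA) size and 5'-base profiling with heterologous spike-in
    normalization, and a fully specified synthetic-data generator with
    planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
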