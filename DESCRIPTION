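Package: ribopause
Title: Codon-Resolved Ribosome Pausing and Translational Efficiency from
    Ribo-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Codon-resolved analysis of ribosome-profiling data: exact
    placement of 28-29 nt ribosome footprints on transcript models, P-site
    assignment with length-dependent offsets, 3-nt periodicity quality
    control, codon-by-ribosome-site occupancy tables with mutant versus
    wild-type differentials, translational-efficiency (TE) log2 fold
    changes with permutation-based significance and Benjamini-Hochberg
    correction, per-transcript codon-usage statistics, and a seeded
    synthetic Ribo-seq/RNA-seq generator that emits ground truth for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
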