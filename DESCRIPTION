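Package: orphanrna
Title: Discovery and Characterization of Transcripts Hidden from a Reference
    Genome Using Unmapped RNA-Seq Read Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for recovering transcripts that are absent from a
    reference genome assembly from paired-end RNA-seq reads whose two mates
    both fail to map. Provides quality and PCR-clone screening of read pairs,
    a greedy overlap assembler with a paired-end scaffold joining algorithm,
    RPKM quantification with expression-frequency association between cancer
    and normal tissue samples, synteny-based nearest-gene assignment through
    a better-assembled proxy species, a Poisson enrichment caller for histone
    marks over off-reference loci, discovery-saturation curve fitting with a
    one-site binding model, and a seeded synthetic-data generator with
    planted ground truth for end-to-end validation. All user-facing functions
    take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    stringi,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    Biostrings,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
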