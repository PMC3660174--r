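Package: venomshift
Title: Two-Stage Venom-Gland Transcriptome and miRNA Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated desk-scale pipeline for studying the ontogenetic
    venom composition shift in pitvipers from paired newborn/adult venom-gland
    sequencing. Provides reference-guided toxin isoform inference from long
    reads (consensus calling, variable-residue annotation, a binomial
    sequencing-error model of contig distinctness, CD-HIT-style protein
    clustering), RPKM toxin-family quantification with NOISeq-sim
    no-replicate differential expression, small-RNA adapter processing and
    miRNA clustering with per-stage abundance comparison, and miRanda-style
    seed-and-energy miRNA target scanning, together with a synthetic-data
    generator that emulates the two-stage study design so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
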