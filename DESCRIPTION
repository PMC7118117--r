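Package: bescreen
Title: Design and Analysis of Base-Editor Substitution-Mutation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for CRISPR-guided cytidine-deaminase (base editor)
    substitution-mutation screens. Designs sgRNA libraries against annotated
    coding sequence with enumeration and classification (silent, missense,
    nonsense) of every mutation introducible through the C-to-T activity
    window, computes CFD-based off-target specificity scores, quantifies
    editing outcomes from amplicon deep-sequencing reads (quality masking,
    protospacer extraction, indel classification, per-position substitution
    efficiency, codon-level allele and co-conversion haplotype tables), counts
    spacers in pooled-screen reads with normalized log2 fold-change
    enrichment, and assigns guides to single cells with maximum-likelihood
    estimation of multiplicity of infection and detection rate under a
    zero-truncated Poisson capture model. Includes simulators that generate
    mini-genomes, edited amplicon reads, selection screens, and cell-guide
    capture records with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
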