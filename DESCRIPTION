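Package: mitocomp
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of insects, built around the
    37-gene circular mitochondrial genome. Reads and writes annotated
    mitogenomes (GenBank flat files, TSV feature tables), computes base
    composition and AT/GC strand-skew statistics, codon usage and relative
    synonymous codon usage (RSCU) under the invertebrate mitochondrial code,
    and calls start and stop codons including atypical AAN starts and
    incomplete T/TA stops. Extracts signed circular gene orders, compares
    them to the ancestral insect arrangement (breakpoint distance, moved
    genes, event classification) and enumerates single
    tandem-duplication-random-loss (TDRL) scenarios that explain an observed
    rearrangement, such as the trnQ-NCR-trnI-trnM cluster of dynastine
    scarab beetles. Also scans for gene overlaps, intergenic spacers,
    sequence motifs, homopolymer runs and exact tandem repeats, locates and
    characterizes the control region, and generates fully annotated
    synthetic mitogenomes with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
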