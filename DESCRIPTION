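Package: cpscan
Title: Common Peptide Motif Extraction and Protein Family Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts deterministic peptide motifs (common peptides) from
    protein-family corpora with a continuation-probability boundary detector,
    builds an overlap-merged motif feature space, and runs downstream family
    analyses: permutation-null Pearson similarity between families, kingdom
    origin classification of motifs, hypergeometric enrichment of
    mitochondrial sequences with false-discovery-rate control, structural
    class signature discovery, functional-site overlap statistics, and
    cross-family shared-motif detection. Includes a synthetic corpus
    generator with planted motifs, clone groups and site annotations so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
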