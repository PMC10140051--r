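Package: orthoprospect
Title: Discovery of Taxonomically Restricted Proteins from Multi-Species
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for discovering taxonomically restricted,
    eco-responsive, unannotated proteins across de novo transcriptomes of
    related species. Covers assembly quality statistics (Nxx, GC content,
    core-gene completeness), six-frame single-best ORF prediction with
    completeness classification, Smith-Waterman protein homology scoring
    with Karlin-Altschul E-values, Markov clustering of multi-species
    proteomes with ortholog-cluster set algebra (sharing orders,
    shared-by-all, foreign-member purging), taxonomic similarity-profile
    scanning with emergence-point calling corroborated by a
    neighbor-joining stem-length check, and read-level contamination
    screening against a COI marker panel. A synthetic-data generator
    produces multi-species proteomes, transcriptomes, annotation panels,
    differential-expression lists and reads with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    dplyr,
    ggplot2,
    generics,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
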