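Package: thawvir
Title: Viral Population Ecology for Soil Viromes Along a Permafrost Thaw
    Gradient
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for virome-based viral community ecology in
    habitat-structured soils, modelled on particle-enriched viromes from a
    permafrost thaw gradient (intact palsa, partially thawed bog, fully
    thawed fen). Dereplicates assembled contigs into species-level viral
    populations (vOTUs) at 95% average nucleotide identity over 80% of the
    contig length, quantifies and detects populations by read recruitment
    (90% read identity, 75% breadth of coverage), groups genomes into
    approximately genus-level viral clusters with a hypergeometric
    gene-sharing network and Markov clustering, predicts microbial hosts
    from CRISPR spacers and nucleotide similarity, and computes
    community-ecology statistics (diversity indices, Bray-Curtis
    ordination, habitat sharing, collector curves, codon-usage profiles).
    Includes a fully seeded synthetic-community generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
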