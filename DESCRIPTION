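Package: bandpattern
Title: Pattern Analysis of Dominant Marker Band Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pattern analysis for dominant (presence/absence) molecular marker
    data such as EST-SSR band scores. Provides per-marker diversity statistics
    (band and banding-pattern frequencies, allele counts, unbiased gene
    diversity, Shannon's information index, Botstein polymorphic information
    content), the normalized squared Euclidean dissimilarity between
    accessions or bands and its simple-matching similarity complement, UPGMA
    dendrograms with optimal leaf ordering (seriation by subtree flips),
    group cuts, un-centered principal component biplots coloured by dendrogram
    groups, dendrogram-ordered heatmaps, a synthetic band-matrix generator
    with planted population structure, and an end-to-end pipeline. Bundles the
    marker panel and accession metadata of a published survey of 56 cucumber
    (Cucumis sativus) landraces genotyped with 28 EST-SSR markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
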