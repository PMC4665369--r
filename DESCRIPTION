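Package: mthia
Title: Heterologous Inferential Analysis of Mitochondrial 16S rRNA Variants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the disruptive potential of rare human
    mitochondrial large-subunit (16S) rRNA variants by heterologous
    inferential analysis (HIA). The package filters variants by their
    rarity in sequence populations, maps them between mtDNA (rCRS) and
    rRNA residue numbering, places them in structural context (atomic
    contacts, base-pair detection and classification, glycosidic
    conformation, least-squares superposition with iterative outlier
    pruning, and cross-structure residue equivalence), scores residue
    conservation on a 0-2 scale, and assigns each variant a
    disruptive-potential category from an encoded evidence profile.
    Synthetic generators provide sequence populations, ideal A-form RNA
    duplexes, alignment columns and evidence profiles with known ground
    truth for testing every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
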