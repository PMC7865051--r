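Package: venomcrp
Title: Annotation, Classification and Molecular Evolution of Venom Cysteine-Rich Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for spider-venom cysteine-rich peptide (CRP)
    repertoires. Annotates precursor regions (signal peptide by rule grammar, propeptide
    terminated by a Processing Quadruplet Motif, mature peptide, C-terminal processing and
    amidation), extracts and classifies cysteine frameworks against an inhibitor-cystine-knot
    (ICK) centred template registry, clusters precursors into families by global identity
    under scaffold compatibility, builds neighbor-joining trees on Poisson-corrected
    p-distances, estimates region-wise synonymous/non-synonymous rates with the original
    Nei-Gojobori (p-distance) method and a bootstrap Z neutrality test, matches theoretical
    peptide masses under disulfide and amidation hypotheses to observed MALDI mass lists,
    and summarises cross-species evolutionary trends. A seeded synthetic-data generator
    emulates CRP precursor architecture and codon evolution under a controllable dN/dS so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    ape,
    Biostrings,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
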