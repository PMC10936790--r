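Package: smartdb
Title: Small Ranked Tailored Reference Databases for Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs compact, species-tailored reference genome databases
    for comparative genomics of prokaryotes, in particular genomic-island
    (GI) discovery. Genomes within each species are ranked by assembly
    quality and by a greedy maximum-diversity criterion on MinHash sketch
    distances; per-species databases are capped in size and filled
    phylogenetically from the closest species on the taxonomy species
    tree, never reaching beyond the taxonomic order. Shared database
    compositions are deduplicated so that far fewer databases than
    species are needed. Also provides evaluation statistics for GI
    support: recovery curves over nested database sizes, taxonomic
    omission yields, support-origin fractions, and support decay over
    phylogenetic distance, together with a fully seeded synthetic
    release generator for testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
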