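Package: mitorearrange
Title: Mitogenome Annotation Statistics and Gene-Order Rearrangement Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of circular mitochondrial genomes:
    feature-annotation table statistics (intergenic spacers and gene overlaps,
    partition lengths, AT/GC composition and skews, start/stop codon
    inventories, relative synonymous codon usage under the invertebrate
    mitochondrial code), a signed circular gene-order algebra (canonical
    forms, adjacency sets, breakpoint distance), and rearrangement operators
    for the tandem duplication - (non-random/random) loss - recombination
    family of models: whole-genome tandem duplication, transcription-polarity
    based gene loss, 3'-3' recombination joins, tandem duplication-random
    loss (TDRL) translocation, and segment inversion.  Event scenarios can be
    replayed and verified against observed gene orders, single-event
    explanations enumerated by brute force, and synthetic genomes and evolved
    gene orders generated with controlled statistical structure.  Ships the
    annotation table and gene orders of the millipede Polydesmus sp.
    GZCS-2019 together with the inferred rearrangement scenario that derives
    its gene order from the arthropod ancestral arrangement.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
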