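Package: mthet
Title: Mitochondrial Heteroplasmy Analysis for Mutation-Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for characterizing mitochondrial DNA
    heteroplasmy in mutation-accumulation (MA) experiments on small circular
    mitochondrial genomes, modeled on bottlenecked Caenorhabditis briggsae
    isolates. Provides annotated-genome domain types with homopolymer census
    and direct-repeat discovery, a Wright-Fisher single-bottleneck lineage
    simulator with transmission bias, a paired-end read simulator with planted
    ground truth, read merging and exact deduplication, a seed-and-extend
    mapper for circular references with split alignments across large
    deletions, a low-frequency heteroplasmy caller with binomial significance
    and strand-bias filters, direct-repeat-mediated large-deletion detection
    from split reads, per-site per-generation mutation-rate estimation from
    summed frequency differences, and nuclear-normalized mtDNA copy-number
    comparisons with nonparametric tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
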