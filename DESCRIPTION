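Package: synpaint
Title: In Silico Chromosome Painting and Karyotype Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative chromosome-evolution toolkit for squamate-style
    karyotypes. Partitions a query genome into fixed-length markers, filters
    homology hits against target genomes and chains consecutive markers into
    syntenic blocks (in silico chromosome painting); quantifies the dispersion
    of each query chromosome's blocks across target scaffolds with the Simpson
    Dominance Index and its reciprocal, the effective number of target
    chromosomes; computes per-window GC content, genic fraction and repeat
    fraction tracks and contrasts macro- against microchromosomes with
    rank-sum tests; assigns scaffolds to chromosomes from linked gene markers
    and curates artificially merged microchromosome scaffolds by detecting
    composition shifts at candidate breakpoints. A built-in simulator
    generates query genomes with macro/micro composition structure, derives
    target genomes by fusion, fission, translocation and inversion with a
    ground-truth homology map, and emits noisy hit tables, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
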