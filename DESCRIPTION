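Package: rRNAfrag
Title: Comparative Analysis of Fragmented Mitochondrial rRNA Genes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing fragmented (discontinuous)
    ribosomal RNA genes on circular mitochondrial genomes, modeled on
    the split large-subunit rRNA of cupped oysters (Crassostrea).
    Provides covariation statistics (mutual information, chi-square)
    over RNA alignment columns with greedy base-pair prediction,
    template-based secondary-structure mapping with domain-presence
    calls, EST-driven gene-boundary inference from polyadenylation
    evidence, circular-coordinate fragment-separation arithmetic,
    fragment sequence statistics (length, A+T content, pairwise
    identity matrices), in-silico PCR with IUPAC-degenerate primers
    including a splicing-test decision rule, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
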