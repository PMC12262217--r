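Package: shmbench
Title: Benchmarking Substitution Models of Antibody Affinity Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates models of somatic hypermutation (SHM) and selection on
    their ability to predict amino-acid substitutions along B-cell receptor
    lineages. Parent-child pairs of nucleotide sequences are scored under
    three frameworks: per-site nucleotide mutation rates aggregated to codon
    substitution probabilities (NT), the same combined with per-amino-acid
    selection factors (NT-AA), and per-site amino-acid probability tables
    such as language-model output (AA). Branch lengths are optimized per
    pair by maximum likelihood, and models are compared with four metrics:
    overlap of observed and expected substitution-count distributions,
    R-precision of predicted substitution sites, substitution accuracy, and
    perplexity of conditional substitution probabilities. A synthetic-data
    module simulates parent-child pairs under a known mutation-selection
    process so that every component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
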