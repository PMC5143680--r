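Package: cohortvar
Title: Alignment-Free Variant Calling in Targeted Sequencing Cohorts with
    Colored de Bruijn Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls sample-specific variants in targeted long-read amplicon
    sequencing of patient cohorts without aligning reads. Reference sequences
    (splicing variants and known-SNP haplotypes) and per-sample read sets are
    represented as explicit-edge colored de Bruijn graphs; paths present in a
    sample but absent from the reference graph are enumerated, anchored, and
    decomposed into atomic alterations by minimal edit operations; each
    alteration's count ratio is then tested against a null distribution
    obtained by resampling reads from the pooled cohort, so that recurrent
    sequencing artifacts (for example homopolymer deletions shared across
    samples) are separated from private mutations. Includes a synthetic-cohort
    generator with a circular-consensus-like error model, truth-table scoring
    utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
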