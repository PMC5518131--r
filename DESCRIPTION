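Package: tandemscope
Title: Tandem Repeat Detection, Repeat-Capture Evaluation and Hybrid Scaffolding at Desk Scale
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for studying how genome assemblies represent tandemly
    repeated sequence. Calls tandem repeat pairs from genome self-alignments
    (PAF or nucmer show-coords tables), classifies how an assembly captures
    each reference repeat (one scaffold, two scaffolds, or underrepresented),
    identifies tandem gene clusters from all-vs-all protein similarity via
    Markov clustering, estimates gene copy number from read-depth ratios and
    from qPCR delta-CT with standard-curve slope correction, and provides the
    synthetic long-range mate-pair scaffolding stages (mate sampling, exact
    mapping, link bundling, greedy layout, coverage-based filtering and
    splitting). A synthetic-data generator plants tandem arrays with known
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
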