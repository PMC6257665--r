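Package: divpick
Title: Diversity-Driven Compound Selection for Screening Library Design
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for selecting structurally diverse small molecules when
    assembling a screening (tangible) compound library. Implements hashed
    linear-path fingerprints with OR-folding, a versioned 166-bit structural
    key set, nine Tanimoto-based similarity schemes including Min/Max/Avg
    consensus metrics and concatenated descriptors, Jarvis-Patrick clustering
    over thresholded neighbor tables, scaffold classification by cyclicity
    (SCA), a two-phase Seed/Refill diverse-selection protocol with a random
    baseline, and diversity-validation statistics (valid-cluster counts,
    average maximal inter-cluster similarity, scaffold-consistency histograms,
    largest-cluster oversampling, selection-overlap distributions) together
    with a full benchmark grid runner. A deterministic synthetic-library
    generator with planted, size-skewed scaffold families supports end-to-end
    testing without any external compound catalogue.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
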