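Package: mlfas
Title: Similarity Scoring for Multi-Layered Protein Feature Architectures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares proteins by their multi-layered feature architectures
    (Pfam/SMART domains, transmembrane segments, low-complexity and
    coiled-coil regions). Overlapping, redundant same-layer annotations are
    resolved during the pairwise comparison by maximizing the architecture
    similarity over all alternative non-redundant realizations, represented
    as maximal sets of mutually compatible feature instances. Provides the
    multiplicity, positional and combined (FAS) similarity scores, uniform
    and abundance-driven feature weighting with ad-hoc minimum weights, an
    exhaustive path-pair search plus a linear greedy/priority heuristic for
    highly redundant architectures, e-value-based and unresolved baseline
    scorings, outlier flagging for ortholog groups, a seeded synthetic
    architecture generator, and readers for a native annotation JSON dialect
    and InterProScan 5 TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
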