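Package: TEmodules
Title: Module Detection and Modular Classification of Transposable Element Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the sequences of a transposable-element family into
    modules: flexible assemblies of exact maximal repeats separated by
    length- and similarity-constrained spacers. Maximal repeats are
    enumerated with a generalized suffix-array index, assembled greedily
    into flexible repeats under the length and edit-distance conditions,
    and placed as non-overlapping modules by decreasing sequence support.
    Reverse (palindromic) and truncated module occurrences are detected,
    sequences are clustered on their modular profiles with Ward
    hierarchical agglomerative clustering, and results are written as a
    composition table, a Newick tree and an SVG rendering of the
    segmentation. A seeded generator of synthetic families with planted
    module architectures supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    xml2,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
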