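Package: ctsnet
Title: Cell Type-Specific Gene Networks and Disease Gene Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cell type-specific gene interaction networks by combining
    cell-annotated single-cell or single-nucleus expression data with a
    referenced tissue-specific weighted gene network, and identifies
    statistically significant cell type-specific disease gene modules.
    Per-gene cell-type specificity is the minimum fold change of mean
    expression (CPM) between the cell type of interest and every other cell
    type; a cell-type score standardizes specificity per gene by its median
    and interquartile range across cell types. Genes whose score exceeds a
    threshold induce a cell type-specific subnetwork of the reference
    network; connected components of disease-associated genes within that
    subnetwork are candidate disease gene modules, assessed by a permutation
    null on the largest connected component among random gene draws, with
    Benjamini-Hochberg false discovery rate control. Includes synthetic-data
    generators with planted markers and planted network modules for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
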