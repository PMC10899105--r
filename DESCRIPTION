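Package: minipath
Title: Error Correction for DNA Microscopy Adjacency Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and correction of two artifact classes in
    sequencing-based image reconstruction (DNA microscopy) adjacency data:
    spurious crosslinks, removed by thresholding weighted indirect-path
    values of length three, and fused nodes, detected by normalized-cut
    partitioning of each node's two-step neighbor subgraph and split into
    their constituent polonies. Includes a diffusion-based Poisson
    adjacency simulator with ground-truth error ledgers, a spectral plus
    Poisson maximum-likelihood layout reconstructor, and quality metrics
    (Procrustes disparity, k-nearest-neighbor overlap, split overlap,
    true/false positive rates against the ledgers).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
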