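Package: dnproj
Title: Projectome Analysis of Descending Neuron Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for organizing and analysing catalogs of descending
    neurons (DNs), the cells that carry information from an insect brain
    into the ventral nerve cord (VNC). Provides a validated tabular data
    model for polarity-annotated innervation catalogs, binary innervation
    matrices under smooth/varicose polarity filters, correlation-distance
    average-linkage hierarchical clustering of neurons and neuropils,
    bipartite brain-to-VNC connectivity matrices with pathway ranking and
    convergence scores, census summary statistics, anterior-posterior
    neurite density profiles from labeled voxel volumes, and a seeded
    synthetic-connectome generator with planted pathway structure for
    end-to-end testing against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    tiff
Config/testthat/edition: 3
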