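Package: mecnet
Title: Community Assembly and Co-Occurrence Networks in Microbial Electrolysis Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing microbial electrolysis cell (MEC) experiments
    end to end. Computes electrochemical performance metrics from current
    traces (5-min rebinned current, peak current, lag time, total charge by
    trapezoidal integration, and coulombic efficiency from substrate
    consumption); Hill-number alpha diversity, pairwise Hill dissimilarity,
    a richness- and depth-preserving Raup-Crick null model, and the Mantel
    test; and signed microbial co-occurrence networks from ASV count tables
    via prevalence/abundance filtering, phylogenetic merging of
    near-identical ASVs, Spearman rank correlation and a from-scratch SparCC
    estimator with dual-criterion edge validation, plus summary network
    properties (edge density, modularity, clustering). A synthetic-data
    module generates batch-cycle current traces and compositional count
    tables with planted associations so the whole pipeline is testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    igraph,
    MASS,
    phytools,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
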