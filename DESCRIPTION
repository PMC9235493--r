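Package: hiblock
Title: Hierarchical Block-Wise Association Discovery Between Paired
    High-Dimensional Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers groups of associated features between two
    high-dimensional datasets measured on the same samples (for example a
    microbiome profile paired with a metabolome).  Every feature pair is
    tested with a nonparametric association measure (Spearman, Pearson,
    mutual information, normalized mutual information, Chatterjee's xi, or
    distance correlation), a single global Benjamini-Hochberg threshold is
    fixed over all pairwise p-values, and each dataset's features are
    clustered by average linkage.  The two cluster trees are then descended
    jointly: a coupled pair of clusters is reported as a significant block
    when at most a false-negative-tolerance fraction of its member pairs
    fails the global threshold, and otherwise the block is cut along the
    tree whose split yields the larger Gini impurity gain.  Includes a
    synthetic paired-data simulator with planted association blocks,
    power/false-discovery benchmarking against naive all-against-all
    testing, and block heatmap ('hallagram'), clustermap and diagnostic
    visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse,
    jsonlite
Config/testthat/edition: 3
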