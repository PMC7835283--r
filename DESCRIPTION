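Package: ictalnet
Title: Directed Seizure Network Analysis from Intracranial EEG and Tractography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of epileptic seizure networks from stereotactic
    EEG (SEEG) and diffusion tractography. Computes the asymmetric nonlinear
    correlation coefficient h2 between electrode contacts over clinically
    delineated seizure events, derives baseline-thresholded directed event
    graphs with weak and strong edge classes, characterizes graph motifs by
    cosine vertex similarity and average-linkage hierarchical clustering,
    tests per-pair correlation changes across seizure phases with exact
    Wilcoxon signed-rank statistics under Benjamini-Hochberg false discovery
    rate control, and counts streamlines connecting labeled electrode regions
    of interest. Includes a synthetic SEEG and streamline-phantom generator
    with planted directed coupling so every stage is testable without patient
    data, plus EDF and TCK file input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    yaml,
    igraph,
    ape,
    signal,
    RNifti,
    ggplot2
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
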