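Package: nerveLR
Title: Ligand-Receptor Interactome Analysis of Peripheral Nerve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the paracrine signaling environment of the
    injured peripheral nerve from bulk and single-cell expression data.
    Implements anchor-gene thresholding of bulk profiles to call expressed
    ligands, per-cell-type detection-fraction statistics from sparse UMI count
    matrices with a 2 percent detection rule, proteomics-anchored receptor
    repertoire calling for target neuron populations, database-driven
    prediction of unidirectional ligand-to-receptor interaction networks, and
    mock-bulk differential Pearson correlation coordinates for single cells.
    Ships transcribed reference tables for regression testing and a synthetic
    data generator emulating sparse droplet single-cell RNA-seq counts,
    rank-structured bulk profiles and partially sensitive surface proteomics.
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
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
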