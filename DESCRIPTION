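Package: allomix
Title: Detecting Mixing-Induced Transcriptional Responses in Donor-Multiplexed scRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether pooling peripheral blood mononuclear cells
    (PBMCs) from unrelated donors during multiplexed single-cell RNA-seq
    sample preparation induces a detectable transcriptional response.
    Provides a synthetic multi-donor PBMC count generator with ground truth
    and a controllable injected alloreactivity effect, sample-tag
    demultiplexing with Hamming-distance barcode correction and
    classification-bias diagnostics, quality-control filtering and
    marker-based cell type annotation, cell-type composition shift tests,
    and a balanced-subsample Jensen-Shannon divergence workflow with a
    donor-label permutation null for comparing group expression states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
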