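Package: tilsim
Title: Multiscale Agent-Based Simulation of Tumour-Immune Checkpoint Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional on-lattice agent-based simulator of the interplay
    between a growing tumour and tumour-infiltrating CD8+ T cells under PD1/PDL1
    checkpoint regulation. Cancer cells proliferate, migrate, acquire PDL1
    expression under immune attack and suppress cytotoxic T cells on contact;
    effector T cells are recruited from tumour vasculature at a rate driven by the
    neoantigen profile (mutational burden and antigen strength) and the dead-cell
    signal, and their local proliferation is fuelled by a diffusing IL-2 field
    solved with an alternating-direction-explicit scheme. The package also
    implements the downstream analytics: label smoothing and connected-component
    tumour-region extraction, central cross sections with Euclidean
    distance-to-boundary maps, rim-restricted PDL1 biomarker scores with ROC
    evaluation over rim-depth thresholds, simulated anti-PDL1 treatment, and
    Latin-hypercube / partial-rank-correlation global sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    lhs,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
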