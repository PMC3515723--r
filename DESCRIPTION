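Package: petfc
Title: Functional Connectivity Analysis of PET rCBF Region-of-Interest Signals
Version: 0.1.0
Authors@R: person("Maintainer", "petfc", email = "petfc@example.org", role = c("aut", "cre"))
Description: Tools for region-of-interest functional-connectivity analysis of
    H215O PET regional cerebral blood flow images: Gaussian smoothing, first
    eigenvariate extraction over ROI masks, partial correlation controlling for
    total intracranial activation, Fisher r-to-z comparison of connectivity
    between treatment sessions with Benjamini-Hochberg adjustment, voxelwise
    paired-t maps with sign-flip permutation cluster inference, and association
    of connectivity with clinical treatment response. Includes a synthetic
    cohort generator with known ground truth, and a minimal NIfTI-1 reader and
    writer, so the full pipeline is testable without real PET data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
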