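Package: infodyn
Title: Algorithmic Information Dynamics of Executable Biological Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compression-based analysis of the dynamics of executable
    (state-based) biological models. Ships a synchronous agent-based
    emulation of a regulatory T cell / naive helper T cell immune
    simulation on a 2D grid, a tab-delimited state-file format, normalized
    compression distance (NCD) computation with an LZMA2 backend, event
    detection on consecutive-state NCD series, non-metric multidimensional
    scaling of state trajectories, and convergence/divergence flow maps of
    information flow with 2D kernel density estimation. Supports wild-type,
    knock-out (IL-10, IFN-gamma, CTLA-4; partial efficiencies), initial
    cell-ratio, and randomized-parameter experimental conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    KernSmooth,
    rlang,
    stats,
    utils,
    graphics,
    parallel
Suggests: testthat (>= 3.0.0), optparse, jsonlite
SystemRequirements: liblzma (xz-utils development headers)
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
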