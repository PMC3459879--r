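Package: loopmodes
Title: Coupling of Catalytic Loop Motions to Intrinsic Collective Dynamics of Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much an enzyme's intrinsic collective dynamics,
    predicted by the anisotropic network model (ANM), drive the catalytic-loop
    reconfigurations observed across its crystal structures. Provides coarse
    C-alpha structure handling, iterative Kabsch ensemble superposition,
    principal component analysis of conformer ensembles, ANM normal modes,
    overlap and cumulative-overlap statistics between experimental deformations
    and predicted modes, segment (loop) overlaps, weighted-average overlap
    profiles over mode and sequence windows, a random-orthonormal-mode null
    model with enhancement factors, and a synthetic-ensemble generator with a
    planted mode-loop coupling for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    tools,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
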