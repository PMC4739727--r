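Package: fibrogel
Title: Multi-Scale Mechanics of Fibroblast-Driven Fibrin Gel Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates short-term structural remodeling of fibroblast-seeded
    fibrin gels with a coupled multi-scale finite-element model: cross-linked
    fiber-network representative volume elements (RVEs) supply a
    volume-averaged Cauchy stress to a trilinear hexahedral macroscopic mesh,
    cell traction is modeled as incremental shortening of fiber reference
    lengths in cellular elements, and gels can be held under Fixed or Free
    in-plane constraints. Also provides the companion image-analysis
    operators (normalized cross-correlation microsphere tracking, FFT-based
    fiber orientation tensors and the alignment index alpha), displacement
    and explant-morphology statistics, and synthetic bead/fiber image
    generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
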