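Package: pcr4d
Title: Four-Dimensional Dose Simulation for Scanned Carbon-Ion Therapy
    with Phase-Controlled Rescanning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates scanned carbon-ion pencil-beam delivery to moving
    lung tumors on synthetic ten-phase respiratory phantoms.  Builds
    field-specific target volumes from water-equivalent path length
    (WEPL) envelopes over respiratory phases, optimizes spot weights for
    a uniform field, simulates timed layer-by-layer delivery with
    phase-controlled rescanning and optional respiratory gating,
    accumulates per-phase doses to the reference exhale phase through
    known deformation fields, and reports dose-volume metrics (D95,
    Dmax, Dmin, homogeneity index, lung V20) together with delivery
    times across rescan-number, gating, and field-number grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
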