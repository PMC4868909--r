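Package: stereoWTA
Title: Adaptive Stereoscopic Disparity Cells from Time-Staggered
    Winner-Take-All Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Behavioral simulator of an adaptive stereoscopic-disparity
    system inspired by the columnar organization of ocular dominance in
    visual cortex. Provides a time-staggered winner-take-all (ts-WTA)
    model of competing synapse pairs, disparity-selective cells built as
    grids of ts-WTA units that learn a preferred disparity from interlaced
    binocular patterns, a patch-splicing stereo pipeline that estimates a
    per-pixel disparity map by letting a bank of trained cells compete as
    filters, diffusive coupling between cells, and a reaction-diffusion
    lattice model of disparity-map formation with continuity, diversity
    and cluster statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
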