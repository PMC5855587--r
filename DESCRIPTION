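Package: afmpull
Title: Single-Molecule AFM Force-Spectroscopy Analysis of Tethered
    Ligand Unbinding and Polymer Peeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscope (AFM)
    force-distance curves from single-molecule pulling experiments on
    mineral and other solid surfaces. Generates ground-truth-labelled
    synthetic retract curves (worm-like-chain tether ramps terminating
    in abrupt rupture, non-specific adhesion artefacts, peeling
    plateaus, Gaussian baseline noise); detects and classifies rupture
    events with an extension-window filter; estimates the most probable
    unbinding force as the mode of a Gaussian fitted locally around the
    tallest histogram peak, including multi-peak decomposition; computes
    binding frequencies with Wilson confidence intervals and
    mode-difference confidence intervals; quantifies polymer peeling
    work and per-residue adsorption energies; models multivalent
    binding configurational statistics; and calibrates cantilever
    spring constants by the thermal-noise (equipartition) method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
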