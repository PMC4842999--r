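Package: nanopsd
Title: Quantification of PSD95 Nanocluster Architecture from Super-Resolution Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the nanoscale organisation of postsynaptic
    density protein 95 (PSD95) from two orthogonal super-resolution modalities:
    pixel images from gated stimulated emission depletion (g-STED) microscopy
    and localisation tables from photoactivated localisation microscopy (PALM).
    Provides a ground-truth synaptic scene simulator, seeded-watershed
    detection and splitting of postsynaptic densities (PSDs) and their
    constituent nanoclusters, single-molecule peak fitting, DBSCAN cluster
    definition and nearest-neighbour-weighted rendering, line-profile FWHM and
    ellipse morphometry, pair-correlation analysis with Monte-Carlo envelopes,
    object-based juxtaposition analysis with rotation controls, and per-mouse
    cohort aggregation with ANOVA/Tukey comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
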