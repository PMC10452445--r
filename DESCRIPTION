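Package: octlumen
Title: Lumen Segmentation and 3D Microvessel Quantification for OCT Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for visualizing and quantifying micro-luminal (vessel)
    structures in optical coherence tomography (OCT) image stacks of
    three-dimensional vascularized hydrogel cultures, such as in-vitro
    blood-brain-barrier models. Provides stack geometry conversion
    (y-stacked x-z cross-sections to z-stacked x-y frames), depth
    truncation and per-frame histogram equalization; lumen segmentation by
    a morphological image-processing chain with circular region-of-interest
    masking and by a trainable random-forest pixel classifier; patch
    split/stitch plumbing for external patch-based detectors; depth-resolved
    Cohen's kappa evaluation against ground truth; 3D connected-component
    vessel quantification (open/closed classification, minimum-caliper
    diameters, Crofton lateral surface areas) feeding the effective
    permeability coefficient Pe = PSe/A; and a synthetic tubular phantom
    generator with exact analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
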