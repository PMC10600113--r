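Package: paleojaw
Title: Skull Biomechanics and Jaw Mechanics Evolution in Ankylosaurian
    Dinosaurs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative biomechanics of the ankylosaur feeding apparatus.
    Implements the dry-skull chain for jaw adductor muscle force estimation
    from volumetric reconstructions (fibre length, physiological
    cross-sectional area, isometric stress), third-class lever models of
    bite force and mechanical advantage at multiple bite points,
    mesh-weighted arithmetic mean (MWAM) summaries of per-element finite
    element stress output with paired model comparison, stratigraphic
    "equal" time-calibration of cladograms from first/last appearance data,
    maximum likelihood Brownian motion ancestral state reconstruction of
    mandibular mechanical advantage, and phylomorphospace coordinates.
    Ships transcribed unilateral muscle and lever measurements for
    Euoplocephalus tutus (AMNH 5405) and Panoplosaurus mirus (ROM 1215),
    plus seeded simulators for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
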