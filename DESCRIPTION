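Package: panorama
Title: Label-Free Single-Particle Detection and Sizing from Ratiometric
    Plasmonic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, sizing and counting of single nanoparticles -- in
    particular small extracellular vesicles (sEVs) -- from label-free
    plasmonic transmission microscopy of gold-nanodisk sensor surfaces.
    Implements the ratiometric intensity-ratio (IR) image, the statistical
    detection threshold IR = 1 + 3*sigma + 0.005, peak-contrast extraction,
    a quadratic contrast-to-diameter calibration with sEV/large-EV
    classification, and time-lapse aggregation of cumulative binding with
    before-wash/after-wash comparison. A physics-grounded synthetic image
    generator (plasmonic forward model, Gaussian particle footprints,
    camera noise, rigid drift, push-pull binding schedule) provides seeded
    ground-truthed acquisition series so the whole pipeline is verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
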