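Package: phantomEF
Title: Mapping tDCS-Induced Electric Fields in Spherical Head Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcranial direct current stimulation
    (tDCS) voltage recordings made in spherical head phantoms instrumented
    with the 21-electrode 10-20 system. Builds the spherical electrode
    geometry at four insertion depths (surface, one third, two thirds and
    the full diameter), re-centres coordinates on the recording reference,
    converts measured voltage differences into electric-field estimates
    (EF = voltage difference / distance to reference), imputes sites hidden
    under stimulating pads by neighbour averaging, summarises the per-depth
    field distribution, and renders scalp-style topographic maps on the
    concentric recording spheres. A quasi-static point-source forward
    simulator generates synthetic recording sets for standard montages so
    the whole pipeline can be exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
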