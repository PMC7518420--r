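Package: mucoscape
Title: Spatial Quantification of Host-Microbe Architecture in Colonic Sections
Version: 0.1.0
Authors@R: person("Mucoscape", "Developers", role = c("aut", "cre"),
    email = "maintainers@mucoscape.example.org")
Description: Tools to quantify the spatial organization of the gut microbiota
    relative to the colonic mucosa in multichannel fluorescence microscopy
    (FISH plus immunofluorescence). Generates binary mucosal and luminal
    masks by channel thresholding, estimates inner mucus layer thickness from
    minimal distances between mask edges, quantifies per-compartment mean
    fluorescence and volumetric bacterial density, classifies mucosa-associated
    biofilms by the density/contact/span rule, and fits thermoreversible
    gelation temperature sweeps with a four-parameter dose-response sigmoid.
    Includes a calibrated synthetic phantom generator of colonic cross-sections
    with known ground truth, so the whole pipeline is testable without raw
    images, plus minimal multi-page TIFF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
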