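Package: myonuc
Title: Force-Balance Models of Myonuclear Positioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Interacting-particle modelling of nuclear positioning in
    multinucleated muscle cells. Simulates overdamped motion of nuclei under
    candidate microtubule-mediated force laws in rectangular cell geometries,
    screens the 216-model force family against spatial pattern criteria in two
    filtering stages, calibrates the surviving models against nuclear position
    data, and provides closed-form strip-model analysis of the single-file to
    double-file pitchfork bifurcation, spatial point-pattern statistics
    (nearest-neighbour distances, file classification, zigzag correlations),
    an anisotropic-stress nuclear shape model, and a synthetic-data generator
    emulating the measured cell populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
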