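Package: icptelemetry
Title: Wireless-Power Coverage, SAR Compliance and Qualification Analytics for an Intracranial Pressure Microimplant
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for a wirelessly powered intracranial-pressure
    (ICP) telemetry implant. Computes the quasistatic magnetic field of a
    circular wand coil from the closed-form elliptic-integral solution, maps
    worst-case-orientation powerability over a voxelized head volume by
    minimax optimization on the unit sphere, applies IEEE C95.1 duty-cycle
    arithmetic to peak-spatial and whole-body SAR exposure tables, qualifies
    sensor accuracy and zero-point drift against NS28-derived tolerances with
    Arrhenius (Q10) accelerated-aging time mapping, and extracts clinical ICP
    waveform metrics (mean ICP, cardiac pulse-wave amplitude, posture-stratified
    longitudinal summaries). Every input the pipeline needs can be generated
    synthetically with seeded, reproducible generators, so no external data
    are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
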