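Package: glomplast
Title: Analysis of Olfactory Go/No-Go Learning and Intrinsic Optical Signal Glomerular Imaging
Version: 0.1.0
Authors@R: person("Glomplast", "Maintainers", email = "maintainers@glomplast.org", role = c("aut", "cre"))
Description: Tools to analyse olfactory go/no-go discrimination behaviour and
    widefield intrinsic optical signal (IOS) imaging of olfactory bulb
    glomeruli. Provides trial scoring against lick-bin criteria, block-wise
    discrimination performance across odorant dilution series, time-resolved
    bootstrap estimation of reaction times from beam-break traces, delta-R/R
    glomerular response quantification with reference-map ROI detection,
    respiration frequency analysis, group-level summaries (trained, exposed,
    naive), and a Boltzmann psychometric linkage between glomerular input
    strength and discrimination accuracy. A seeded synthetic-data generator
    with programmed ground truth supports end-to-end validation of every
    stage without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
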