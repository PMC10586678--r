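Package: nicknet
Title: Simulation of Neural Computation on Nicked-DNA Fractional Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of a DNA neural engine in which values in
    [0,1] are encoded as the fraction of double-stranded DNA molecules nicked
    at a given site. Multiplication is performed by independent double nicking
    (a fraction of a fraction), dot products by row-wise droplet merging in a
    valved microcell array under 1/k enzyme dosing, readout by toehold-mediated
    strand displacement with magnetic-bead separation, and step/sigmoid
    activation by seesaw gates. Includes the stochastic logic gate algebra with
    a bitstream Monte Carlo oracle, a discrete-event model of the microfluidic
    valve protocols with replayable traces, layer-wise execution of
    nonnegative-weight neural networks with serialization over a finite array,
    and closed-form latency and area models of the lab-on-chip with
    least-squares calibration of stage constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    rtracklayer,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
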