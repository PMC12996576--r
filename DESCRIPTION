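Package: petaif
Title: Arterial Input Function Analysis for Small-Animal Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing arterial input functions (AIF) in
    small-animal dynamic PET studies: calibration of continuous arterial
    detector traces against manual blood samples, parametric (Feng) input
    function fitting with onset-delay estimation, dispersion correction,
    image-derived input function (IDIF) construction from left-ventricle
    and liver time-activity curves with partial-volume correction,
    objective curve-feature extraction including break-point detection,
    reversible two-tissue compartment and Patlak kinetic modelling, and
    correction of repeated-injection experiments. A synthetic-data
    generator emulates the experimental knobs of a mouse PET protocol
    (injection volume and duration, blood withdrawal rate, catheter
    dispersion and delay, tracer kinetics, frame averaging and count
    noise) so that every processing step can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
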