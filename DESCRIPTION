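Package: photokin
Title: Kinetic Analysis of Photochromic Fluorescent Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form kinetic models and fitting machinery for
    biphotochromic fluorescent proteins: irreversible green-to-red
    photoconversion (consecutive first-order formation and
    photodestruction), reversible on/off photoswitching (bi-exponential
    decays with opposed or same-sign components), and thermal relaxation
    of the chromophore. Includes bounded nonlinear least-squares fitting
    with multistart initialization and AICc model selection, multi-cycle
    photofatigue analysis with variant-behaviour classification, emission
    spectrum peak localization and blue-shift quantification,
    Henderson-Hasselbalch pKa titration fitting, brightness computation,
    a generic first-order reaction-scheme integrator that serves as an
    independent oracle for the closed forms, and seeded synthetic-data
    generators emulating the illumination experiments so every pipeline
    stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
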