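Package: cnsync
Title: Carbon-Nitrogen Release Synchronization Analysis for Swine Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing in vitro two-phase (gastric/intestinal)
    digestion time-courses and the synchronization of dietary carbon and
    nitrogen supply. Computes interval nutrient-release rates from cumulative
    release curves, the four glucose/nitrogen synchronization indices
    (Relative G/N, Relative G/AA, G/N, G/AA) over the early intestinal
    window with Syn/Asyn classification, marker-based ileal digestibility
    (AID, basal endogenous losses, SID), total-tract digestibility and
    nitrogen/energy balance fractions, starch substitution-gradient diet
    design, and a first-order-kinetics simulator that generates release
    curves and a virtual ileal-cannulated pig trial with known truths for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
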