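Package: cordillera
Title: Integrative Phylogeography of Arctic-Alpine Plant Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the Quaternary history of mountain
    plant radiations from heterogeneous evidence: ensemble paleodistribution
    modelling with vote maps and glacial-refugium stability surfaces,
    time-stratified dispersal-extinction-cladogenesis (DEC) likelihoods for
    biogeographic hypothesis testing, environmental-space niche overlap
    (Schoener's D) with equivalency and similarity randomization tests,
    nucleotide diversity and coalescent neutrality statistics, conversion
    between substitution-scaled and calendar-scaled divergence times, and
    categorical/discriminant morphometrics. A synthetic-data module
    generates every input (climate grids, occurrences, chronograms, tip
    ranges, alignments, morphology samples) with known ground truth so the
    whole pipeline runs end to end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    MASS,
    Matrix,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
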