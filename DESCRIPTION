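Package: truedist
Title: True Evolutionary Distances from Gene Orders under Rearrangements,
    Duplications and Losses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates genome evolution on mixed linear/circular chromosomes
    under a unified stochastic model of rearrangements (inversion,
    translocation, fusion, fission, linearization, circularization),
    segmental duplications and single-gene losses, and estimates the true
    number of evolutionary events separating two gene-order genomes.  The
    estimator summarises a genome relative to a reference as an integer
    vector over gene and adjacency copy-number classes plus shared/distinct
    adjacency and telomere counts, iterates an O(kC) one-step expectation
    recursion for that vector, and returns the event count (and optionally
    the duplication/loss probabilities) whose predicted expected vector is
    closest in 1-norm to the observed one.  Includes a GRIMM-style
    gene-order parser/writer, a seedable event simulator with full event
    logs, and experiment drivers for trajectory-accuracy and
    estimator-accuracy studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
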