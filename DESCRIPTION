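Package: neoconn
Title: Burst Coincidence and Laminar Connectivity Analysis for the Neonatal Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying functional and anatomical corticocortical
    connectivity in newborn rodent cortex. One arm extracts multi-unit spike
    times from extracellular recordings, detects burst discharges, and measures
    pairwise burst coincidence and onset-lead directionality against jittered
    and joint-ISI-dithered surrogate nulls, including cross-correlogram
    significance in the monosynaptic 5-15 ms window. The other arm fits 3D
    pial and subplate boundary surfaces, computes normalized cortical depth of
    retrogradely labeled somata, assigns laminar identity from relative layer
    thickness schemes, and tests laminar enrichment of backlabeled cells
    against expected neuron proportions (chi-square goodness of fit plus exact
    binomial tests). A synthetic-data generator with known ground truth
    replaces unavailable raw recordings and confocal volumes so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
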