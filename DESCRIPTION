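Package: dynppi
Title: Dynamic Circadian Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts time-of-day specific protein-protein interactions from
    circadian expression profiles. Detects 24-hour periodicity of expression
    time series with a Fourier score and permutation-based empirical false
    discovery rates, approximates complex abundance by the product of the two
    partners' expression profiles to call rhythmic ("dynamic") interactions
    with circadian phases, analyses the resulting network (topology,
    degree-preserving null models, party/date hub classification, temporal
    co-expression enrichment, coupling of functional categories via dynamic
    edges), and scores circadian phenotypes from oscillatory bioluminescence
    reporter time series via damped-cosine fitting. Includes simulators for
    every input class so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
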