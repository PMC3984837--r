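Package: erpselect
Title: EEG Channel Selection for P300 Classification by Hybrid Particle
    Swarm Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint selection of EEG channels and classifier regularization
    for the classification of P300 event-related potentials in auditory
    oddball experiments.  A multiobjective hybrid real-binary particle
    swarm optimization searches over one real coordinate (the shrinkage
    parameter of a regularized Fisher discriminant classifier, encoded
    exponentially) and 64 binary channel-inclusion bits, maximizing the
    geometric mean of the cross-validated target and nontarget accuracies
    while minimizing the number of channels used.  Includes a synthetic
    oddball-EEG generator, the standard epoch preprocessing chain
    (zero-phase Butterworth band-pass, baseline correction, block-average
    decimation), a stratified evaluation harness with score-averaged
    trials, Pareto-front extraction, and channel selection-frequency maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
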