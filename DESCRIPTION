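Package: resteeg
Title: Resting-State EEG Band Power and Coherence Biomarkers of Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested pipeline from 14-channel resting-state EEG and a
    delayed-match-to-sample behavioral session to band-power tables,
    magnitude-squared coherence networks, and electrode- and edge-wise
    Pearson correlation maps against retrieval accuracy and speed.
    Includes preprocessing (band-pass, average re-reference, bad-channel
    rejection, a simplified artifact subspace reconstruction), Welch
    spectral estimation at 0.25 Hz resolution, behavioral task scheduling
    and scoring, and a synthetic-cohort generator with planted effects so
    that every stage is testable end to end without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
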