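Package: statecoding
Title: Behavioral-State Coding Analysis of Extracellular Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for prefrontal tetrode recordings across
    behavioral states (neutral baseline, cued fear recall, capsaicin-induced
    tonic pain): common-median referencing, Butterworth bandpass filtering,
    MAD-thresholded spike detection, duplicate-unit pruning by shared-spike
    and refractory-violation rules, global rate-coding classification against
    an empirically calibrated same-state log-ratio null, behavior-episode-
    locked permutation testing of sliding-window binned rates, Ward-linkage
    waveform cell typing, and dual-label (Fos/tag) overlap statistics with
    chance-level calculation. Ships a ground-truth synthetic-data generator
    (inhomogeneous Poisson spike trains, episode timelines, voltage traces,
    cell-count tables) so every stage is verifiable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
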