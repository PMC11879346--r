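Package: triplettag
Title: Frequency-Tagged EEG Analysis of Auditory Statistical Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design triplet-structured tone sequences for auditory
    statistical-learning experiments, forward-simulate multichannel EEG with
    controllable phase locking at the tone (3.33 Hz) and triplet (1.11 Hz)
    presentation rates, preprocess and epoch the recordings, and quantify
    neural tracking of the hidden triplet structure via inter-trial phase
    coherence (ITC) and the Triplet Learning Index (TLI), including
    time-resolved learning curves with logarithmic fits, cluster-based
    permutation group comparisons, and brain-behavior correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
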