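Package: AuxREfusion
Title: Fuzzy Dempster-Shafer Data Fusion for Auxin-Response Element
    Prediction in Plant Promoters
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts Auxin-response elements (AuxREs) in plant promoter
    sequences by fusing heterogeneous evidence with Dempster's rule of
    combination. Candidate motif windows are described by overrepresentation
    features (position from the ATG, a background z-score, occurrence and
    promoter density) and by composition features (Z-curve parameters and GC
    fraction projected onto two linear discriminant axes). Each feature pair
    is mapped through a fuzzified region-mass table to a basic probability
    assignment over the two-hypothesis frame {AuxRE, not AuxRE}, the three
    assignments are combined with the orthogonal sum, and windows are called
    at a credibility threshold. Ships a synthetic training fixture, a
    spike-in gold-standard benchmark with a sensitivity/PPV metric panel,
    and a promoter scanner with TSV/BED output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: MotifDiscovery, SequenceMatching, Transcription, Classification
RoxygenNote: 7.3.3
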