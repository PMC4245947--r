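Package: koinr
Title: Knockout-Implemented Normalization for ChIP-seq Peak Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: False-positive correction for transcription-factor ChIP-seq
    using a matched knockout (KO) sample as the peak-calling control.
    Implements a compact local-Poisson (lambda-local) peak caller, dual
    peak calling with swapped treatment/control, subtraction of peaks
    shared between wild-type and knockout, a normalized tag-count
    fold-change filter, detection of recurrent extreme-signal
    ('hyper-ChIPable') regions, peak annotation against a gene model,
    position-weight-matrix motif statistics, and a paired WT/KO read
    simulator with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
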