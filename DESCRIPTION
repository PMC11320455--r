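Package: provpack
Title: Engineering and Sequencing QC of AAV Proviral Plasmids
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: In-silico engineering of self-complementary AAV proviral plasmids
    that reduce cross-packaging of bacterial backbone DNA (ATG-scrubbed human
    intron stuffer arms, three-frame stop cassettes, CTCF insulator placement,
    packaging-capacity checks), together with the sequencing quality-control
    side: a seeded simulator of packaged-genome populations, alignment-free
    k-mer classification of short reads into insert, backbone, helper-plasmid
    and host categories, long-read truncation-hotspot and origin-composition
    profiling, and the cross-sample summary statistics (paired t tests on log
    yields, dose-contamination arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
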