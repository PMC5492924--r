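Package: envubiq
Title: Genus-Environment Association Mining and Genomic Correlates of
    Microbial Ubiquity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating prokaryotic genomic characteristics
    (genome size, 16S rRNA gene copy number, intragenomic 16S diversity,
    COG functional-class profiles) to the ubiquity and environmental
    preferences of the corresponding taxa. Implements genus-environment
    association mining from environmental sample observation tables
    using one-sided Fisher exact enrichment tests with Benjamini-Hochberg
    false discovery rate control, a randomized frequency-table null
    control, genus-level trait aggregation with an annotation-completeness
    filter, rank-based and regression trait comparisons across ubiquity
    and environment groups, and a per-COG ubiquity regression screen.
    A synthetic-data generator with planted associations and trait
    gradients makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
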