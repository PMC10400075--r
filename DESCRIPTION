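Package: sexsplice
Title: Sex-Specific Alternative Splicing Analysis Across Developmental Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Catalogs the seven local alternative-splicing event classes
    (skipped exon, mutually exclusive exons, alternative 5'/3' splice site,
    retained intron, alternative first/last exon) from a genome annotation,
    quantifies percent-spliced-in (PSI) per event from transcript-level
    abundances, tests differential splicing between sample groups with a
    replicate-label permutation test, and classifies condition-dependent
    events into known, new, and non sex-specific splicing categories across
    developmental time points. Also integrates chromatin occupancy data:
    peak-to-nearest-splice-junction distances, bound-gene fractions, and
    scale-regions metagene profiles with a resampled active-gene baseline.
    A synthetic-data module generates annotation, abundance, peak, and
    coverage fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
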