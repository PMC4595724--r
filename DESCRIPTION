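Package: oriMFA
Title: Replication Origin Mapping by Marker Frequency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of genome-wide replication profiles for
    circular archaeal chromosomes. Provides a population-level multi-origin
    replication model for asynchronous cultures, simulators for two-channel
    marker-frequency microarrays and deep-sequencing read counts, the standard
    marker frequency analysis (MFA) processing chain (per-probe ratios, outlier
    exclusion, probe binning, sliding-window smoothing, read windowing), a peak
    caller with relative firing-efficiency estimation and dormant-origin
    activation calls from parent/mutant profile comparison, and a sequence-based
    predictor of cdc6-associated origins from inverted origin-recognition-box
    (ORB) repeats in upstream intergenic regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
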