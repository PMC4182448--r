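Package: fuzzycrm
Title: Fuzzy Frequent-Itemset Mining of Cis-Regulatory Modules from
    Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects putative cis-regulatory modules (CRMs) from genome-wide
    transcription factor binding site (TFBS) annotations. Binding sites are
    grouped by one-dimensional average-linkage clustering, each cluster is
    rendered as a fuzzy transaction through a trapezoidal membership function,
    and statistically significant co-occurring transcription factor
    combinations are extracted with a fuzzy frequent-pattern-tree miner using
    the minimum t-norm. Each reported combination carries a fuzzy support, a
    binomial p-value under an independence null model, and an overlap-aware
    refit that places one non-overlapping site per factor at every locus.
    Includes a crisp baseline mode, a synthetic TFBS landscape generator with
    planted modules for validation, and readers for BED, GFF3 and tabular
    site annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
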