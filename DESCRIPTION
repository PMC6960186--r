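Package: fwrnet
Title: Fuzzy Weighted Recurrence Networks of Multi-Channel Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs fuzzy weighted recurrence networks from multi-channel
    raster images and computes their weighted network statistics. Local image
    windows are summarized by per-channel Frobenius norms, the resulting
    feature vectors are partitioned by fuzzy c-means, and a max-min fuzzy
    relation over the memberships defines a weighted adjacency matrix whose
    average weighted clustering coefficient and characteristic path length
    quantify spatial stain texture. Includes whole-slide tiling with
    background exclusion, a cohort pipeline that aggregates per-specimen
    metrics into tumor-to-biopsy ratios and relates them to survival, and
    generators for synthetic immunohistochemistry-like images and cohorts
    used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    png,
    tiff,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
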