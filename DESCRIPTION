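Package: mazeqtl
Title: Haplotype QTL Mapping for Group-Tested Olfactory Y-Maze Learning
    and Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scoring and genetic mapping of group-tested olfactory
    learning and memory assays in multiparent recombinant inbred line
    (RIL) panels such as the Drosophila Synthetic Population Resource
    (DSPR). Converts terminal y-maze chamber counts into two-decision
    binomial scores (climbing and choice correctness), preference-adjusted
    performance metrics, and acuity proportions; selects extreme-
    performing lines conditional on founder haplotype at prior QTL peaks;
    and scans the genome with per-position binomial generalized linear
    mixed models on founder haplotype probabilities, using likelihood-
    ratio tests, Storey q-values for positive false discovery rate
    control, and odor-differential suggestive-peak detection. Includes a
    seeded synthetic-data generator producing founder-mosaic haplotype
    maps and fly-level behavioral outcomes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
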