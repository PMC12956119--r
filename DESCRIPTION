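Package: storysim
Title: Automated Story Similarity and Retelling Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of structural similarity between story
    retellings in repeated-reproduction (serial recall) designs. Stories are
    segmented into sentences as a proxy for events; content similarity counts
    events remembered in common under per-sentence within-story similarity
    thresholds, sequence similarity rank-correlates matched event order, and
    the two are multiplied into a combined score in [-1, 1]. Includes
    retelling-lineage evolution metrics (stabilization, consistency,
    modification), cross-participant dispersion via multidimensional scaling
    and the Standard Distance Deviation with permutation tests, pluggable
    sentence-similarity backends (lexical overlap and averaged word vectors),
    and a synthetic serial-reproduction corpus generator with controllable
    forgetting, reordering, paraphrase, intrusion, and schema convergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
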