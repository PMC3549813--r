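Package: fitrank
Title: Rank-Based Similarity Search for Yeast Fitness Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Platform-independent similarity between genome-wide fitness
    profiles of yeast deletion collections. Arbitrary fitness scores
    (fold-ratios, z-scores, p-values, ranks, binary hit calls, tiered
    genetic-interaction classes) are converted to strict rank profiles; a
    dynamic-programming rank-cutoff optimizer then finds the pair of rank
    cutoffs minimizing the cumulative hypergeometric overlap p-value and
    reports the overlap significance (-log10 p) and Tanimoto overlap score.
    Includes a three-letter-keyword YAML profile format, a file-based profile
    repository with batch search and two-way result filtering,
    genetic-interaction prediction, and synthetic profile generators with
    planted overlap for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
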