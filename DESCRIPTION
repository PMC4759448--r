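Package: meristo
Title: Meristograms for Serial Hook Morphometrics of Acanthocephalans
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes Meristograms: standardized, moving-average-smoothed
    curves of serial variation in acanthocephalan proboscis-hook
    morphometrics (blade length, base width, estimated cross-sectional
    area and robustness ratio) against percent-position along the hook
    row. Includes validation of the triangular hook-area approximation by
    linear regression against digitized areas, a comparative pipeline
    (feature matrix construction, principal component analysis, UPGMA
    clustering under several distance metrics with Newick export), a
    synthetic hook-collection generator with known positional trends for
    testing, plotting functions, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    patchwork,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
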