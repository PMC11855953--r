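Package: hostpref
Title: Host Preference Analysis for Epiphytic Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies host preference (host exclusivity) of epiphytic
    species from long-format presence records of epiphyte-by-host
    observations in grid cells nested in geographic areas. Computes
    exclusivity counts and percentages at local (per-area) and regional
    (pooled) scales, permutation-based host-preference accumulation curves
    with min/max envelopes, and Venn-style partitions of a focal host's
    epiphyte flora across areas. Includes a specialist/generalist occurrence
    simulator for validation and parameter-recovery studies, and a small
    command-line interface with run manifests for reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
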