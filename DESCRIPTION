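Package: ki67grid
Title: Grid-Based Whole-Slide Ki67 Scoring and Recurrence-Score Concordance
Version: 0.1.0
Authors@R:
    person("Ki67grid", "Maintainers", email = "maintainers@ki67grid.org",
           role = c("aut", "cre"))
Description: Tools for grid (tile) based scoring of Ki67 immunohistochemistry
    on whole slides: pooled average, top-k hotspot and hottest-spot labeling
    indices with the standard 100-tumor-cell QC filter; a Monte-Carlo
    simulation of the International Ki67 Working Group (IKWG) manual scoring
    protocol (global and weighted average over four sampled fields); cohort
    concordance analysis of Ki67 bins, Nottingham grade and a combined
    grade/hotspot risk rule against 21-gene Recurrence Score categories,
    with Pearson chi-square tests; and a synthetic slide and cohort generator
    with planted proliferation hotspots for end-to-end testing without any
    image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
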