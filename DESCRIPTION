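Package: circadam
Title: Circadian Rhythm Analysis for Drosophila Activity Monitor Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of circadian locomotor rhythmicity from TriKinetics
    Drosophila Activity Monitor (DAM) beam-break recordings: monitor file
    input/output, binning and light-phase annotation, Lomb-Scargle and
    chi-square (Sokolove-Bushell) periodograms with significance thresholds,
    automated rhythmic/arrhythmic classification with rhythm power and
    free-running period estimates, double-plotted actogram matrices, and
    morning/evening anticipation indices. Also provides the
    Jonckheere-Terpstra-Kendall (JTK-Cycle) nonparametric rhythmicity test
    with exact null distributions for gene-expression time courses,
    standard-curve qPCR quantification with reference-gene normalization,
    background-subtracted nuclear-fluorescence quantification, Kruskal-Wallis
    with Dunn's post hoc and one-way ANOVA with Tukey's post hoc group
    comparisons, and a seeded synthetic-data module that generates beam-break
    cohorts, expression time courses and nucleus images with the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
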