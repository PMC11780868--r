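Package: g4therm
Title: G-Quadruplex Motifs and Thermal Adaptation in Prokaryotic 16S rRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and scoring of putative G-quadruplex (G4) and i-motif
    forming sequences by a QGRS-style candidate enumerator with a per-motif
    G-score and a G4Hunter-style sliding-window propensity scorer; per-species
    G4 frequency, score and stability summaries across thermal groups
    (psychrophile to hyperthermophile); neighbour-joining trees from Kimura
    2-parameter distances with bootstrap supports; phylogenetic generalized
    least squares under Pagel's lambda, Pearson correlation and one-way ANOVA
    with normality pre-checks; conservation profiles and presence/absence of
    orthologous G4 loci across aligned 16S sequences; and a fully seeded
    synthetic comparative-genomics data generator plus an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
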