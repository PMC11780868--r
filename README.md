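# g4therm

G-quadruplexes (G4s) are four-stranded nucleic-acid structures formed by
stacked tetrads of guanines in G-rich sequence. In prokaryotes their
frequency and stability in the region encoding the 16S rRNA track optimal
growth temperature (T_opt): hyperthermophiles tend to carry more, and more
stable (three-tetrad), G4 motifs in their 16S genes than mesophiles or
psychrophiles. `g4therm` packages the computational side of that comparative
analysis for microbiologists and molecular evolution researchers:

- **Motif detection** — a QGRS-style enumerator for quadruplex-forming
  G-rich sequences `G{g} N{l1} G{g} N{l2} G{g} N{l3} G{g}` (defaults: max
  length 30 nt, min G-group size 2, loops 0–36 nt) with a per-motif G-score,
  and a G4Hunter-style sliding-window propensity scorer (window 25,
  threshold 1.2) for genome-scale scans. Both strands are supported; C-rich
  mirror signals (i-motif-prone) are reported as minus-polarity hits.
- **Per-species metrics** — GC content, G4 frequency (motifs/kb), score
  summaries, a stability flag (best score > 25, the cut separating
  three-tetrad from two-tetrad motifs), and thermal-group classification
  (psychrophile < 20 °C ≤ mesophile < 45 °C ≤ thermophile < 80 °C ≤
  hyperthermophile).
- **Phylogenetics** — Kimura 2-parameter distances
  (`d = -½ ln(1−2P−Q) − ¼ ln(1−2Q)`), neighbour-joining trees, bootstrap
  supports, Newick I/O.
- **Comparative statistics** — phylogenetic generalized least squares (PGLS)
  under Pagel's λ (profile-ML or fixed), Pearson correlation, and one-way
  ANOVA with D'Agostino–Pearson normality/lognormality pre-checks and
  Tukey–Kramer pairwise comparisons.
- **Conservation** — alignment column profiles (sequence-logo frequencies
  and information content), presence/score matrices of orthologous G4 loci,
  and identification of G4-disrupting substitutions.
- **Synthetic data** — a fully seeded generator (ultrametric Yule tree,
  Brownian-motion T_opt, 16S-like sequences evolved along the tree whose GC
  content and planted G4 density/stability rise with temperature, seeded
  motif disruptions, ground-truth registry), plus an end-to-end pipeline.

## Worked example

```r
library(g4therm)

# detect and score quadruplex candidates in a telomeric-repeat-like sequence
enumerate_qgrs("GGGTTAGGGTTAGGGTTAGGG")[17, c("start", "end", "g", "score")]
#>    start end g score
#> 17     0  21 3    39

score_qgrs(3, c(1, 1, 1))   # three tetrads, minimal loops
#> [1] 41
score_qgrs(2, c(1, 1, 1))   # two tetrads: below the stability cut of 25
#> [1] 20

# run the full synthetic analysis at the default "paperlike" preset
cfg <- validate_config(outdir = "g4therm_out", seed = 1, verbose = FALSE)
report <- run_pipeline(cfg)
print(report)
#> g4therm pipeline report
#>   species: 96, motifs: 959, seed: 1
#>   PGLS 16S G4 score ~ T_opt: slope 0.1189 (p = 3.91e-15, lambda = 0.000)
#>   Pearson r (16S GC, T_opt): 0.921
#>   stable-G4 ratio by group:
#>     psychrophile     0.000
#>     mesophile        0.000
#>     thermophile      0.556
#>     hyperthermophile 1.000
```

The report says: across 96 simulated species, the mean G4 score of the
16S-like region increases by ≈ 0.12 score units per °C of optimal growth
temperature after correcting for shared ancestry (PGLS), 16S GC content is
strongly positively correlated with T_opt, and the fraction of species with
a stable (three-tetrad, score > 25) G4 rises monotonically from
psychrophiles to hyperthermophiles. All intermediate outputs (FASTA,
metadata, motif BED/TSV, metrics, Newick tree, PGLS panel, stable-ratio
table, JSON report) are written under `outdir` and are byte-identical when
rerun with the same seed.

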