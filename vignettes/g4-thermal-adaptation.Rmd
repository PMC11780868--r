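---
title: "G-quadruplex motifs and thermal adaptation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G-quadruplex motifs and thermal adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`g4therm` implements a comparative-genomics workflow around one biological
question: do G-quadruplex (G4) motifs in the 16S rRNA region track the
optimal growth temperature (T_opt) of prokaryotes? This vignette documents
the models the package implements, the parameters that matter, the
synthetic-data generator that the test suite exercises, and the design
choices made where the method left room.

## Motif detection

Two complementary detectors are provided.

**QGRS-style enumeration** (`enumerate_qgrs()`) emits every candidate
`G{g} N{l1} G{g} N{l2} G{g} N{l3} G{g}` with G-group (tetrad) size
`g >= min_g`, loop lengths in `[loop_min, loop_max]`, and total length at
most `max_length`. Defaults are max length 30 nt, min G-group 2 and loops
0–36 nt — the settings commonly used for 16S scans. Loops may themselves
contain guanine; `N` breaks G-runs and never scores, a deliberate bias
against false positives on ambiguous sequence. Overlapping candidates are
reduced with `select_nonoverlapping()`: greedy by descending score, ties by
leftmost start then shortest span, which makes the retained set independent
of input order.

Each candidate gets an integer **G-score**

```
score = 21 (g - 1) - round(mean pairwise |l_i - l_j|) - round(mean loop length)
```

with half-up rounding. The QGRS web tool does not publish its scoring
formula, so this one is the package's own: it is calibrated so that
minimal-loop two- and three-tetrad motifs score 20 and 41 (the example
scores reported for a psychrophile and a hyperthermophile motif), rises
strictly with the number of stacked tetrads, falls with loop length and
loop asymmetry, and places the conventional stability cut — score > 25 —
exactly between two- and three-tetrad motifs for all in-range loop draws.
Exact parity with the web tool's numbers is not claimed; anchor agreement
and monotonicity are tested instead.

**G4Hunter-style scanning** (`hunter_regions()`) scores every base: +min(n,
4) inside a maximal run of n guanines, −min(n, 4) inside a run of n
cytosines, 0 otherwise; a window (default 25 nt, the published default) of
mean absolute score ≥ 1.2 qualifies, and overlapping same-sign windows are
merged with the mean recomputed over the merged span. Positive polarity
marks G4-prone regions; negative marks C-rich regions, which are the
i-motif-prone mirror signal on the given strand. A merged region's
recomputed mean can fall slightly below the window threshold; the region is
kept, since each of its constituent windows qualified.

Genome scans default to both strands; 16S scans use the forward strand only
(rRNA is functionally single-stranded), exposed via `strands`.

## Per-species metrics

G4 frequency is reported per kilobase (`1000 * count / length`); the
method's source material never states the unit, but per-kb is the scale on
which published 16S-versus-genome comparisons (≈ 9.8 vs ≈ 1.4) make sense
for ~1.5 kb genes. A species is flagged as carrying a *stable* G4 when its
best motif score exceeds 25; with the score formula above this coincides
with "has a three-or-more-tetrad motif" for default loop ranges, and both
the criterion and the threshold are arguments. An empty motif set reports
count 0 and mean score 0 with an explicit `has_motifs = FALSE` flag rather
than an error — genomes with no hits are legitimate observations. Thermal
groups partition T_opt at 20, 45 and 80 °C.

## Phylogenetics

Kimura 2-parameter distances use transition proportion P and transversion
proportion Q over *usable* sites (pairwise deletion of gaps and N — the
common choice for rRNA alignments):
`d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`. When the logarithms are
undefined the pair is *saturated*; the package raises an error rather than
silently capping, because silent caps distort trees. A `cap` argument
substitutes a configurable maximum for users who want one. Trees are built
by neighbour-joining; negative branch-length estimates are clamped to zero
with the deficit moved to the sister branch (standard practice). Bootstrap
supports resample alignment columns (default B = 1000), drop saturated
replicates with a warning and adjust the denominator. Trees are unrooted;
`root_midpoint()` provides midpoint rooting for display and for PGLS.

## Comparative statistics

PGLS fits `y = Xb + e`, `e ~ N(0, sigma² V(λ))`, where `V(1)` is the
Brownian-motion covariance (shared root-to-MRCA path lengths) and Pagel's λ
scales the off-diagonal. The phrase "λ ∼ 1" in this literature is ambiguous
between *fixing* λ = 1 and *estimating* it by maximum likelihood (the
default of the standard comparative packages); both modes are implemented
and ML is the default. The profile likelihood is evaluated on a 101-point
grid over [0, 1] and refined by golden-section/Brent search to 1e-6; a
dense-grid oracle in the test suite confirms the argmax. With λ = 0 and an
ultrametric tree the fit reduces to OLS exactly, which is also tested. Note
that unconstrained λ (as in some GLS correlation structures) can drift
above 1 into a near-singular covariance with a spurious likelihood spike;
constraining to [0, 1] avoids that pathology, and the package's GLS math is
verified against `nlme::gls` + `ape::corPagel` at fixed λ.

The ANOVA path mirrors a common GraphPad workflow: a D'Agostino–Pearson
omnibus K² pre-check on raw then log10-transformed values decides between
"normal", "lognormal" and "neither" at α = 0.05 (implemented in-package,
with the signed-cube-root kurtosis transform so strongly platykurtic
samples remain defined; it reproduces scipy's `normaltest` to 1e-9 on
frozen fixtures); the one-way F test then runs on the chosen scale and
pairwise contrasts use Tukey–Kramer. Holm-type alternatives were considered
and rejected to keep a single, conventional post-hoc path. ANOVA across
thermal groups does not correct for shared ancestry — a known limitation of
the original analysis design that the package reproduces deliberately; the
PGLS panel is the phylogenetically corrected view.

## Conservation

`column_profile()` returns gap-excluded base frequencies and information
content `IC = 2 - H` bits per column — the numeric content of a sequence
logo; graphics are left to the user. `map_window()` carries 0-based
half-open reference windows through an alignment to each species' own
coordinates; `g4_presence_matrix()` rescans each mapped locus with a 5 nt
flank (tolerating small indel shifts) and records the best G-score or
absence; `disrupting_substitutions()` lists the mismatches/indels inside a
motif footprint, flags those inside the four G-runs, and classifies each
species as forming/non-forming by rescanning. Alignments are consumed, not
computed.

## The synthetic-data generator

`build_dataset()` emulates the observable structure of the real
comparative setting:

- an ultrametric Yule tree (`rphylo`, pure birth), scaled to unit height so
  rates are per total root-to-leaf time;
- a latent temperature trait evolved as Brownian motion (σ² = 100, root
  35 °C, λ = 1), then monotonically rescaled to 10–85 °C with exponent
  `t_skew = 1.6`, so every dataset spans the full thermal range while most
  species land in the mesophile band — mirroring the composition of growth-
  temperature databases (mostly mesophiles, a handful of hyperthermophiles);
- 16S-like sequences: a root sequence at the root GC target is evolved along
  the tree (per-edge substitution probability `1 - exp(-mut_rate * len)`,
  `mut_rate = 0.15` root-to-leaf), then each leaf is nudged to its GC target
  `0.40 + 0.003 * T_opt` (± 0.02 species-level jitter, clipped to
  [0.25, 0.75]) — giving both credible phylogenetic signal for the NJ stage
  and the strong positive GC–T_opt correlation seen in real 16S data;
- planted G4 motifs at a fixed locus grid shared by all species (spacing
  ≈ 62 nt): counts Poisson with expectation rising linearly from 2 motifs
  per sequence at 20 °C to 10 at 85 °C; each motif has three tetrads with
  probability `plogis((T_opt - 70)/7)`, else two; loop draws respect the
  default QGRS maximum motif length; a disruption (one G of one run mutated
  to A/T, which provably removes any motif of the planted G-group size from
  the footprint) is applied with probability falling from 0.5 at 20 °C to
  0.05 at 85 °C. Effect sizes are not published quantities; they were
  chosen once for a clear signal at n = 96 and are documented as arbitrary.

Because all species share locus positions and no indels are simulated, the
equal-length sequences double as an alignment; the conservation module's
gap handling is tested separately on hand-built gapped fixtures. What the
generator does **not** emulate: rRNA secondary structure, codon or
context-dependent substitution, indels beyond motif disruption, horizontal
transfer, and alignment error. Green tests therefore demonstrate
correctness of the computations and recoverability of planted structure,
not that real 16S data satisfy the model.

The default ("paperlike") preset is 96 species and 1.5 kb sequences. For
calibration studies the suite uses a *null* configuration — every
temperature link switched off (flat GC, flat motif rate, constant
tetrad-stability and disruption probabilities) and `mut_rate = 3`, which
makes sequences near-exchangeable so that both the PGLS regression null and
the group-comparison null hold exactly; at 48 species × 800 nt over 500
seeds both tests hold their nominal 5% size. Slope-recovery experiments use
200 datasets of 64 leaves; end-to-end signal checks use 100 seeds of the
full preset. These problem sizes are the package's own choice of a
precision/runtime trade-off.

## Pipeline

`run_pipeline()` executes data → detect → metrics → tree → stats →
conservation → report with a flat key = value configuration
(`validate_config()` reports all violations at once). All outputs
(FASTA/TSV/BED/Newick/JSON) are deterministic given the seed; the report's
numbers are recomputable from the emitted tables, which the test suite
checks. Defaults mirror the stated detection parameters (QGRS max length
30, min G-group 2, loops 0–36). One default deliberately departs from the
source workflow: the pipeline's `bootstrap` defaults to 0 because supports
are not consumed by any downstream stage and dominate runtime at n = 96;
`bootstrap_support()` itself defaults to the conventional B = 1000, and
setting `bootstrap = 1000` in the config restores the full behaviour.

## Numerical notes and known limitations

- Half-up rounding (`floor(x + 0.5)`) is used in the G-score so that scores
  are platform-stable; R's banker's rounding would make .5 cases depend on
  parity.
- NJ inherits `ape::nj` tie handling; on additive matrices the
  reconstruction is exact (tested to 1e-9 against path sums), and the
  negative-branch clamp only activates on noisy matrices.
- `chol()` on a λ-transformed covariance can fail for degenerate trees with
  zero-length cherries; the trait simulator falls back to a 1e-10 jitter.
- The K2P fast path computes all pairs via indicator-matrix products; it is
  exact, but for alignments with tens of thousands of taxa a compiled
  implementation would be preferable.
- Detection is pure R and enumerates candidate tuples; it is comfortably
  fast for 16S-scale sequences and for the synthetic genomes used here, but
  a chromosome-scale QGRS scan should use the Hunter method (as its
  originators intended for genome-wide work).
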