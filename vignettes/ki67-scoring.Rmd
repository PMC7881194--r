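---
title: "Grid-based Ki67 scoring: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based Ki67 scoring: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67grid)
```

## The scoring problem

The Ki67 labeling index (LI) — the percentage of tumor cells with nuclear
Ki67 staining — is a low-cost proliferation measure for ER+/HER2− breast
cancer, but its clinical use is undermined by non-standardized scoring:
the same slide yields very different numbers depending on whether the
pathologist reports a whole-tumor average or a hotspot. `ki67grid`
implements a grid-based formalization of both. The invasive tumor area is
tiled into square grids (300–500 µm, roughly a high-power field); an
image-analysis program counts tumor cells $n_g$ and Ki67-positive tumor
cells $k_g$ in each grid $g$; this package consumes those per-grid counts.

After a QC filter that drops grids with fewer than 100 tumor cells
(strictly fewer: a 100-cell grid is retained), three whole-slide scores
are defined over the valid grids:

* **average** (pooled, global): $A = 100\,\sum_g k_g / \sum_g n_g$ — a
  cell-count-weighted mean, invariant under merging or splitting of
  grids as long as no QC exclusion changes;
* **hotspot**: $H_5$ = the unweighted mean LI of the five highest-LI
  grids;
* **hottest spot**: $H_1 = \max_g 100\,k_g/n_g$.

These satisfy $H_1 \ge H_5$ and $H_1 \ge A$ always; $H_5 \ge A$ whenever
grids carry equal cell counts. The merge-invariance of $A$ is the exact
mechanism behind the near-perfect agreement of average scores across grid
sizes, which the test suite checks via `regrid()`.

Two conventions were genuinely open and are fixed as follows. The
"average of the top five grids" is implemented as the unweighted mean of
the five grid LIs; a pooled-count variant over the same five grids is
available through `hotspot_score(method = "pooled")` for sensitivity
analysis. Slides with fewer than five valid grids (coarse tilings produce
as few as four) are scored over all available grids, with `k_used`
reported, rather than erroring. Ties at the fifth LI are broken by larger
cell count, then grid id — this affects only which grids are *reported*
as the hotspot, never the score.

## The IKWG protocol simulation

The International Ki67 Working Group's manual protocol scores a small
number of fields sampled across staining levels. `run_ikwg_simulation()`
emulates it on grid data:

1. the LI range over valid grids (max − min) is cut in thirds at
   $c_1, c_2$;
2. grids are assigned to levels: **zero** (LI exactly 0), **low**
   ($0 < \mathrm{LI} \le c_1$), **medium** ($c_1 < \mathrm{LI} \le c_2$),
   **high** ($\mathrm{LI} > c_2$); boundaries are upper-inclusive, a
   convention this package fixes since none is standard. A slide with
   zero range puts all non-zero grids in a single level;
3. four fields are allocated across the non-empty levels by
   largest-remainder apportionment of the level proportions (remainder
   ties broken by spare capacity, then level order), capped at level
   sizes, and sampled without replacement;
4. the **global average** pools counts over the four fields; the
   **weighted average** sums, per level, the mean LI of its sampled
   grids times the level proportion.

Two interpretation choices, flagged as such: the exact IKWG field-count
rule is proprietary to its training materials, so proportional allocation
is the default and a one-per-non-empty-level strategy is available via
`strategy = "one_per_level"`; and when a non-zero level receives no pick,
its mass is renormalized over the sampled levels (the zero level always
contributes zero at its full proportion), which avoids a systematic
downward bias from small never-sampled levels. The LI range is computed
over all valid grids including zero-LI grids; `range_over = "nonzero"`
switches that off.

The simulation repeats selection 1000 times (the protocol's published
replicate count) from one seeded RNG stream — no per-replicate reseeding
— so a fixed seed reproduces results bit-exactly. Summaries are the
median and the 2.5th/97.5th percentile interval (percentile CI; type-7
quantiles). On a homogeneous slide both scores collapse to the common LI
with zero-width intervals, a fixed point the tests assert.

## Cohort concordance against the 21-gene Recurrence Score

`rs_category()` bins the Recurrence Score at 0–15 / 16–19 / 20–25 / >25,
the convention of the published concordance tables (not the trial
prose's 16–20/21–25 grouping — the printed cell counts and the "RS > 20"
usage are only consistent with the table convention). `ki67_bin()` uses
half-open decade bins with a closed ≥40 top bin. The combined risk rule
calls a tumor low risk iff grade 1 **or** hotspot < 20 (strict).
`chemo_by_rs()` operationalizes the trial rule — chemotherapy indicated
under 50 when RS > 20, at 50 or older when RS > 25 — with age exactly 50
assigned to the older stratum, following the tables' stratification.

The two published concordance tables ship as plain-text cell counts
(`ki67_reference_tables()`). `expand_reference_table()` inflates a layout
into per-case records carrying representative within-bin values (decade
midpoints 5/15/25/35/45; RS categories mapped to 8/17/22/30) chosen so
that the *classifier logic*, not table reading, reproduces the printed
counts; re-tabulating an expansion is the identity, a round-trip the
tests assert for every layout.

Chi-square tests are plain Pearson, no continuity correction: under that
convention eight of the ten published statistics reproduce from their
printed counts to ±0.02. The remaining two (the younger stratum's hotspot
and grade layouts, printed 30.08 and 25.58) do **not** reproduce
(recomputation gives 36.08 and 26.47); for the hotspot layout the printed
*p*-value 0.0003 matches the recomputed statistic, pointing to a
transcription slip in the printed statistic. These two are excluded from
the reproduction tests and asserted only as documented discrepancies.

## The synthetic-slide generator

No image data ship with the package; `simulate_slide()` generates the
statistical structure the analysis assumes:

* **lattice**: 25 × 26 grids of 300 µm by default, matching the mean
  grid count (~651) of a 300 µm tiling of a typical slide;
* **cell counts**: negative binomial with mean 268.4 (the observed mean
  at 300 µm) and dispersion 0.3 (variance $= \mu + 0.3\mu^2$, CV ≈ 0.55),
  chosen because only means are reported and observed per-grid ranges are
  wide; dispersion 0 degenerates to Poisson;
* **positivity field**: baseline fraction $p_0$ plus $m$ Gaussian bumps
  of amplitude $a$ and width $\sigma$ (in grid units) centered uniformly
  at random, clamped to $[0,1]$; positives are binomial draws. Defaults
  $p_0 = 0.06$, $m = 2$, $a = 0.35$, $\sigma = 2$.

`simulate_cohort()` adds case-level structure: age as an under/over-50
two-point mixture (probability 153/240 under 50, uniform within stratum),
grade with probabilities 0.212/0.646/0.142, and per-case log-normal
baseline (median 0.09, sdlog 0.7) and amplitude (median 0.10, sdlog 0.5)
— the across-case heterogeneity that produces the right-skewed score
distribution. RS is linked to the realized pooled average $A$ by

$$\mathrm{RS} = \mathrm{round}\,\mathrm{clamp}_{[0,100]}\!\left(\beta_0 + \beta_1\sqrt{A} + \beta_2(\mathrm{grade}-2) + \varepsilon\right),\quad \varepsilon \sim N(0,\sigma)$$

with defaults $\beta_0 = 2$, $\beta_1 = 4.4$, $\beta_2 = 4$, $\sigma = 8$.
The square root gives the saturating, non-linear LI–RS relation seen at
low proliferation (a modeling choice, not an estimated law). These
defaults were fixed by calibration runs at $n = 240$ before any test was
written, to land on the stated conditions — median average ≈ 10.6,
hotspot ≈ 2× average, cohort $r(A,\mathrm{RS}) \approx 0.5$ — and have
not been revisited since; across seeds they give median average 10–11,
hotspot/average ratio ≈ 2.2, $r \in [0.45, 0.54]$.

What the generator does **not** emulate: irregular tumor outlines (the
lattice is full and rectangular), spatially correlated cell density,
manual-exclusion patterns (DCIS, lymphoid aggregates), staining or
scanner artifacts, and any real biological LI–RS mechanism. A green test
against synthetic cohorts therefore establishes that the *pipeline*
computes its definitions correctly and that qualitative orderings (e.g.
the IKWG weighted average tracking the pooled average more closely than
the IKWG global average) hold under the assumed structure — not that the
published effect sizes would be recovered on real slides.

## Numerical and degenerate-input conventions

* Scores are percents in $[0,100]$ throughout; all published thresholds
  are on the percent scale.
* Quartiles and percentile CIs use linear interpolation between order
  statistics (`quantile` type 7), fixed and documented.
* A slide whose grids are all excluded raises an "empty slide" error at
  scoring time, not at QC time.
* A grid with zero tumor cells has undefined LI; it is harmless under any
  positive QC threshold and an error otherwise.
* `read_grid_table()` auto-detects tab vs comma from the header and
  validates counts as non-negative integers with
  `positive_cells <= tumor_cells`, naming offending grids.
* Chi-square requires strictly positive margins; degenerate rows or
  columns must be dropped by the caller (the CLI does this before
  testing).

## Known limitations

The package consumes grid-level counts; cell detection and
tumor/non-tumor classification are upstream and out of scope, as are
reproducibility (ICC) analyses of repeated readings, survival endpoints,
and hormone-receptor associations. The IKWG allocation rule and the
weighted-average renormalization are documented interpretations of an
incompletely specified manual protocol; sensitivity switches are provided
for both.
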