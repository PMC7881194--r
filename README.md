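# ki67grid

Grid-based whole-slide Ki67 scoring, IKWG manual-protocol simulation, and
concordance analysis against the 21-gene Recurrence Score (RS).

## Who this is for

The Ki67 labeling index (LI) — the percent of tumor cells with nuclear
Ki67 staining — is a candidate low-cost surrogate for gene-expression
recurrence assays in ER+/HER2− breast cancer, but reported values depend
heavily on the scoring method (whole-tumor average vs hotspot).
`ki67grid` is for pathologists and computational-pathology researchers
who tile the invasive tumor area into square grids (300–500 µm), export
per-grid tumor-cell and Ki67-positive counts from an image-analysis
program, and want reproducible whole-slide scores and downstream
concordance statistics.

## What it computes

Over the valid grids of a slide (QC: grids with fewer than 100 tumor
cells are excluded; exactly 100 is retained), with per-grid counts
$(k_g, n_g)$ and LI $= 100\,k_g/n_g$:

* **average** $A = 100\,\sum_g k_g \big/ \sum_g n_g$ (pooled, global);
* **hotspot** $H_5$ = mean LI of the five highest-LI grids;
* **hottest spot** $H_1$ = maximum grid LI;
* an **IKWG protocol simulation**: grids are split into zero/low/medium/
  high staining levels by thirds of the LI range, four fields are drawn
  proportionally to level size, and the global (pooled over fields) and
  weighted (level-mean × level-proportion) averages are recorded over
  1000 replicates;
* **concordance**: Ki67 decade bins, Nottingham grade and the combined
  risk rule (low iff grade 1 or hotspot < 20) cross-tabulated against RS
  categories (0–15 / 16–19 / 20–25 / >25), with plain Pearson chi-square
  tests and misclassification counts under the age-stratified
  chemotherapy rule (RS > 20 under age 50, RS > 25 at 50+);
* a **synthetic generator** of slides (negative-binomial cell counts,
  Gaussian proliferation hotspots, binomial positives) and cohorts
  (log-normal per-case baselines, RS linked to √average), so the whole
  pipeline is testable without image data.

## Worked example

```r
library(ki67grid)
set.seed(7)

slide <- simulate_slide(slide_sim_params(n_rows = 12, n_cols = 12),
                        case_id = "demo")
score_slide(slide)
#> slide_scores 'demo' (300 um, 137/144 grids valid)
#>   average 13.75  hotspot 39.54 (k=5)  hottest 41.95

run_ikwg_simulation(apply_qc(slide, 100), n_replicates = 1000, seed = 7,
                    keep_replicates = FALSE)
#> ikwg_summary 'demo': 1000 replicates (seed 7)
#>   global   median 11.49 [7.70, 15.81]
#>   weighted median 10.40 [8.10, 13.84]

pearson_chi2(reference_counts("age_ge50", "combined"))
#> Pearson chi-square: X2 = 12.1259, df = 3, p = 0.006964
```

Reading the output: 7 of the 144 simulated grids fail the 100-cell QC;
the pooled average LI is 13.75% while the top-5 hotspot is 39.54% — the
generator plants localized proliferation bumps, so the hotspot score runs
well above the average, as on real heterogeneous tumors. The IKWG
simulation's median weighted average (10.40%) sits close to the pooled
average, its 95% percentile interval quantifying field-selection
variability. The chi-square line reproduces a published combined-risk ×
RS-category table (bundled in `inst/extdata/`) to printed precision.

A command-line wrapper exposes the same pipeline
(`exec/ki67grid score|ikwg|concordance|synth|reproduce-tables`), e.g.

```sh
Rscript exec/ki67grid synth --n-cases 5 --seed 1 --out-dir synth/
Rscript exec/ki67grid score --input synth/ --out scores.tsv
```

## Documentation

See the methods vignette (`vignettes/ki67-scoring.Rmd`) for the scoring
conventions, the IKWG simulation's interpretation choices, the synthetic
generator's calibration, and known limitations.
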