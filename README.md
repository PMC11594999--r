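# flimtex

Label-free texture phenotyping of red blood cells from fluorescence
lifetime imaging (FLIM) matrices.

FLIM assigns every pixel of a microscopy image the mean fluorescence
lifetime (picoseconds) of its emitted photons. In sickle cell disease
(SCD), polymerizing hemoglobin S raises local lifetimes: sickled
erythrocytes show bright membrane-adherent areas, and even
normal-appearing SCD cells can carry small high-lifetime dots. The
scientifically interesting question is whether morphologically normal SCD
cells already differ from healthy cells in the *spatial arrangement* of
their cytoplasmic lifetimes — invisible to the eye, but measurable by
texture analysis. `flimtex` provides that analysis end to end, for
hematology and biophotonics researchers working with per-cell lifetime
matrices:

* **Histogram features** of a rectangular region of interest (ROI) inside
  the cell: mean, SD, skewness, Shannon entropy, 5th/95th percentiles
  (`histogram_stats()`).
* **Rotation-invariant uniform Local Binary Patterns.** Each pixel's `P`
  circular neighbors at radius `R` (bilinear interpolation; default
  `P = 24, R = 3`) are thresholded against the center with
  `s(x) = 1 if x >= 0`; patterns with at most two circular 0/1 transitions
  are coded by their popcount, all others by the sentinel `P + 1`, giving
  `P + 2 = 26` codes:

  LBP^riu2 = Σ s(g_i − g_c)  if U ≤ 2, else P + 1.

  The code histogram and its mean/SD/skewness/entropy are the texture
  descriptors (`lbp_transform()`, `lbp_histogram()`, `lbp_stats()`).
* **Fisher linear discriminant** maximizing
  J(w) = (wᵀ S_B w)/(wᵀ S_W w), with stepwise feature selection on partial
  Wilks'-lambda F statistics, leave-one-out validation (cell- or
  patient-level units), and repeated stratified 50/50 hold-out with macro
  F-score (`fit_lda()`, `stepwise_select()`, `loo_validate()`,
  `holdout_validate()`).
* **Nonparametric group tests** (Mann-Whitney U, Wilcoxon signed-rank,
  Lilliefors/KS normality screen) and table-shaped group comparisons
  (`compare_groups()`).
* **Focus detection**: 8-connected components above a robust threshold, a
  reproducible surrogate for visual counting of high-lifetime dots
  (`detect_foci()`).
* **A synthetic cohort generator** emulating control, non-sickled and
  sickled cell phenotypes with calibrated lifetime moments and a
  class-specific spatial texture model, so the whole pipeline is testable
  without restricted patient data (`generate_cell()`,
  `generate_cohort()`).

## Worked example

```r
library(flimtex)

params <- flim_default_params()      # 175.5 / 193.9 / 253.3 ps class means
co <- generate_cohort(c(control = 27L, scd = 45L),
                      c(control = 10L, nonsickled = 10L, sickled = 5L),
                      params, seed = 1)
co
#> <flim_cohort: 945 cells (control=270, nonsickled=450, sickled=225), 72 patients, seed 1>

feats <- cohort_features(co)         # 6 raw + 4 LBP features per cell

classify_cohort(feats, "patient", seed = 1)
#> Classification at patient level (summary4 features)
#>   selected: lbp_entropy, lbp_skewness, lbp_mean
#>   accuracy 95.8%, LOO 94.4% (n = 72)
#>   hold-out 95.3% +/- 2.9%, macro F 0.95 +/- 0.03

classify_cohort(feats, "cell", seed = 1)
#> Classification at cell level (summary4 features)
#>   accuracy 78.6%, LOO 78.5% (n = 720)
#>   hold-out 78.2% +/- 2.0%, macro F 0.77 +/- 0.02
```

The numbers show the structural signature the pipeline is built to expose:
classifying a *patient* (features averaged over that patient's
normal-appearing cells) is substantially more accurate than classifying a
single cell, because averaging shrinks within-class texture noise; and the
discriminating information lives in the LBP-transformed matrix (here the
code-histogram entropy), not in the raw lifetime histogram alone. A
feature-by-feature group table comes from `compare_groups()`:

```r
keep <- feats$subtype %in% c("control", "nonsickled")
compare_groups(feats[keep, c("lbp_mean", "lbp_entropy")], feats$subtype[keep])
#>       feature mean_control mean_nonsickled statistic      p_value
#> 1    lbp_mean    20.470949       20.425179     69380 1.402732e-03
#> 2 lbp_entropy     1.316605        1.384941     27162 1.765816e-35
```

Whole runs (`run_pipeline()` or `flimtex run --config cfg.txt --out dir
--seed 7`) write the manifest, matrices, feature table, classification
reports, comparison tables, foci counts and a provenance log under one
directory.

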