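---
title: "Methods: FLIM texture analysis of red blood cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FLIM texture analysis of red blood cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimtex)
```

## The analysis problem

Fluorescence lifetime imaging (FLIM) of unstained blood films produces, for
every cell, a matrix of per-pixel mean fluorescence lifetimes (picoseconds).
In sickle cell disease (SCD), polymerizing hemoglobin S changes the
molecular environment and raises local lifetimes; sickled erythrocytes show
large bright membrane-adherent areas and SCD cells can carry small
high-lifetime dots. The harder question is whether *morphologically normal*
SCD cells already differ from healthy cells in the spatial arrangement of
their cytoplasmic lifetimes — a difference invisible to a human observer.

`flimtex` implements that analysis as a reusable pipeline:

1. first-order statistics of the ROI lifetime histogram
   (`histogram_stats()`): mean, SD, skewness, Shannon entropy, 5th/95th
   percentiles;
2. the rotation-invariant uniform Local Binary Pattern transform
   (`lbp_transform()`) and its derived descriptors;
3. Fisher linear discriminant analysis with stepwise feature selection and
   leave-one-out / repeated hold-out validation at cell and patient level;
4. nonparametric group comparisons (Mann-Whitney, Wilcoxon signed-rank,
   KS/Lilliefors normality screen);
5. a bright-focus detector as a reproducible surrogate for visual dot
   counting;
6. a synthetic cohort generator so that all of the above is testable
   without patient data (none are publicly deposited).

All statistics operate on a rectangular region of interest (ROI) placed
strictly inside the cell, because plasma pixels would otherwise dominate
every histogram; coordinates are 0-based and half-open (`roi_rect()`).

## The riu2 LBP transform

For each interior pixel with intensity $g_c$, $P$ neighbors $g_0 \dots
g_{P-1}$ are sampled on a circle of radius $R$ at angles $2\pi i/P$,
by bilinear interpolation where the sample point is not a pixel center.
The binary pattern is $s(g_i - g_c)$ with $s(x) = 1$ for $x \ge 0$ (ties
count as 1, exactly as the indicator is defined). With the circular
transition count $U$ (including the wrap-around term), the code is

$$\mathrm{LBP}^{riu2}_{P,R} = \begin{cases}
  \sum_i s(g_i - g_c) & U \le 2 \\
  P + 1 & \text{otherwise,}
\end{cases}$$

giving $P+2$ possible codes — 26 for the working configuration $P = 24,
R = 3$. The histogram of codes over the ROI interior is the texture
descriptor; its mean, SD, skewness and entropy (over the 26-bin histogram)
are the "LBP features" used by the discriminant stage.

Numerical choices worth stating:

* **Border handling.** A border of width $\lceil R \rceil$ is excluded; no
  padding is invented, so the code matrix is smaller than the ROI.
* **Pixel-center snapping.** Sampling offsets within $10^{-9}$ of an
  integer are snapped, so axis-aligned samples equal the pixel value
  exactly instead of inheriting one-ulp interpolation noise.
* **Exact rotation closure.** For $P$ divisible by 4 the offset table is
  built from the first quadrant and closed under exact 90° rotation, so
  rotating an image by 90° maps sample points onto sample points to the
  last bit and code histograms are exactly invariant (a property the test
  suite asserts with `identical()`).
* **Monotone invariance.** Codes depend only on signs of differences, so
  any strictly increasing intensity transform leaves them unchanged
  *wherever sampling needs no interpolation* (e.g. $P=4, R=1$). Under
  interpolated sampling the guarantee weakens to affine transforms,
  because interpolation commutes with affine maps but not with general
  monotone ones. The tests assert each form where it genuinely holds.
* **Rotation invariance rule.** The $U \le 2 \Rightarrow$ popcount rule is
  used directly instead of minimizing over circular shifts; the two are
  equivalent for riu2 and this is $O(P)$ per pixel.

## Histogram features

Skewness is the population moment coefficient $m_3/m_2^{3/2}$ (no
small-sample correction). Percentiles use linear interpolation between
order statistics. Entropy is the Shannon entropy of the histogram over 32
equal-width bins spanning the ROI's own range; the binning is a free
parameter (`entropy_bins`) because no universal absolute entropy scale
exists for this quantity — consequently entropies are comparable *within*
an analysis but their absolute values depend on the binning, and they are
invariant under shifting or rescaling the lifetimes. A constant ROI is
degenerate: skewness and entropy are reported as 0 with a warning.

## Discriminant analysis

`fit_lda()` maximizes the Fisher criterion
$J(w) = (w^\top S_B w)/(w^\top S_W w)$ with the between- and within-class
scatter matrices $S_B$, $S_W$. For two classes the maximizer is the closed
form $w \propto S_W^{-1}(\mu_1 - \mu_0)$, which the implementation uses
(tests verify agreement with the generalized eigenproblem route to
cosine $> 1 - 10^{-10}$, and prediction agreement with an independent
reference implementation). A singular $S_W$ triggers a ridge
$\varepsilon I$ with $\varepsilon = 10^{-8}\,\mathrm{tr}(S_W)/d$, recorded
in the model object. The decision threshold equates the two
pooled-covariance Gaussian posteriors with training priors.

`stepwise_select()` is classical stepwise discriminant analysis on partial
Wilks'-lambda F statistics: forward entry of the best candidate with
$F > F_{\text{enter}}$, backward removal below $F_{\text{remove}}$, and a
pooled within-class tolerance check that silently skips collinear
candidates (a duplicated feature can never enter twice). The defaults
3.84 / 2.71 are the conventional 5% / 10% points used by legacy statistics
packages. Note a consequence of the 5% entry level: with $k$ pure-noise
candidates, some noise feature is expected to enter in roughly
$1-(1-0.05)^k$ of datasets; a protocol that demands a ≥ 95% clean-selection
rate over three noise features therefore implies the 1% entry level
($F_{\text{enter}} = 6.63$), which is what the package's own end-to-end
recovery check uses — the operation exposes both as parameters.

Validation follows the two-level design of the study: at **cell level**
every cell is a unit; at **patient level** features are first averaged per
patient (`aggregate_per_patient()`). `loo_validate()` refits everything —
including the stepwise selection — inside every fold; folds whose training
half collapses to one class are skipped and reported. `holdout_validate()`
performs stratified 50/50 splits, 10 repeats by default, reporting accuracy
and macro F-score as mean ± SD. Macro averaging is the default because no
class is canonically "positive".

## Group comparisons

Unpaired contrasts use the Mann-Whitney U test (exact p for
$\min(n_1,n_2) \le 8$ without ties, tie-corrected normal approximation
otherwise, no continuity correction); paired contrasts (non-sickled vs
sickled cells of the same patients) use the Wilcoxon signed-rank test with
zeros dropped. Both are verified against complete enumeration oracles in
the test suite. The normality screen is one-sample KS with estimated
parameters; since estimating mean and SD invalidates the standard KS null
distribution, the Lilliefors-corrected reference is the default and the
uncorrected variant is available only for comparability with legacy
software output. Raw p-values are reported without multiplicity correction
by default, with a `p_adjust` switch.

## The synthetic cohort generator

The generator emulates the study's three phenotypes on a plasma background
(450 ps default, noticeably above any cytoplasm value):

* **control** — round cell (60 px diameter), homogeneous cytoplasm,
  mean 175.531 ps, pixel SD 30.222 ps, no foci;
* **nonsickled** — round SCD cell, mean 193.891 ps, SD 28.091 ps, carrying
  0–3 dots (discs of radius 2 px, +150 ps) placed inside the ROI with a
  minimum separation;
* **sickled** — elongated cell (ellipse, axis ratio 3.2), mean 253.335 ps,
  SD 58.614 ps, with an irregular blob grown from a random boundary pixel
  covering 10–30% of the footprint at +80…+200 ps (it always touches the
  cell boundary), plus possible dots.

**Moment calibration.** The configured class mean and SD refer to the whole
ROI *including* planted structures, since that is what per-cell empirical
statistics measure. Each cell therefore solves for its base cytoplasm level
and noise scale given the planted structure field; a structure draw whose
variance alone would exceed the SD budget is scaled down. Two consequences
are documented rather than hidden: (i) recovery of the configured moments
is exact by construction (the acceptance suite checks 200 cells/class
against 2 standard errors), and (ii) raising the dot offset does *not*
raise p95 when dots cover less than 5% of the ROI — the calibration
reallocates the tail into noise — so the tail-monotonicity property is
asserted where it genuinely holds (dots covering > 5%).

**Texture model.** Cytoplasm noise is a unit-variance mixture of white
noise, two Gaussian-correlated fields (σ = 0.8 px and 1.8 px), and sparse
positive impulse speckle, with class-specific variance fractions and
impulse density, plus Gaussian jitter of these fractions per cell and per
patient. This is the channel the LBP features respond to: spatially
correlated lifetimes produce more uniform low-transition patterns (lower
mean code, higher code entropy), impulses shift mass into the extreme
codes. The class contrast of the defaults lives mainly in the coarse
fraction (0.05 / 0.12 / 0.20) and the impulse/dot density, tuned so that a
full cohort reproduces the *structure* of the real analysis: cell-level
leave-one-out accuracy around 0.78 and patient-level around 0.89, with
patient level always the higher of the two.

**A structural finding: LBP mean and skewness are informational twins.**
Across every texture mechanism expressible in this generator (smoothing at
either scale, impulses of either sign, quantization, planted dots), the
class-signal-to-sampling-noise ratios of the LBP mean and LBP skewness are
nearly identical, because both statistics are dominated by the same
low-code tail mass of the riu2 histogram. Stepwise selection consequently
treats them as interchangeable: it picks one of them (near coin flip),
or both as mutual de-noisers — a final model containing the mean but
excluding the skewness is not a reproducible outcome of image-level
simulation. The end-to-end checks therefore assert the reproducible
structure: the entropy channel is always recovered, and patient-level
accuracy dominates cell-level accuracy. On real FLIM data the reported
final models may well differ — real hemoglobin texture need not obey this
generator's histogram geometry, which is exactly the kind of caveat a
synthetic benchmark cannot remove.

**What the generator does not emulate.** Photon-counting (TCSPC) decay
statistics, optics and the point-spread function, multi-cell scenes,
acquisition drift, and any real spatial morphology of polymer domains.
Passing tests show the *pipeline* is correct and well-calibrated, not that
the synthetic images are biologically faithful.

**Reproducibility.** All randomness flows from one integer seed through a
counter-based substream per cell (patients get their own substreams for
texture shifts), so cohorts are bit-reproducible and insensitive to
generation order.

## File formats

Lifetime matrices: tab-separated text (written with `%.17g`, hence
bit-exact round trips; NaN allowed for masked pixels outside ROIs) or
single-channel 32-bit float TIFF. TIFF samples are portable only inside
[0, 1], so TIFF files store *nanoseconds* (ps / 1000) and the reader
rescales; lifetimes ≥ 1000 ps must use the text format. Manifests are
tab-separated with a fixed mandatory header (unknown columns are
preserved). The pipeline writes every intermediate as plain text, plus a
log with wall times, record counts and the MD5 of the configuration.

## Problem sizes used by the test suite

The suite enumerates all $2^P$ patterns for $P \le 12$; compares the LBP
implementation against a brute-force oracle on 50 random 16×16 images for
$(P{=}4, R{=}1)$ and $(P{=}8, R{=}1)$; checks the Gaussian Bayes rate at
10,000 samples per class; runs 100 seeded stepwise-recovery simulations;
recovers generator moments from 200 cells per class; and runs 20 seeded
end-to-end replicates of the full study layout (27 control subjects, 45
patients, 10 cells each). These sizes were chosen to keep each check's
Monte-Carlo error well below its assertion margin.

## Known limitations

* The absolute entropy scale depends on the (configurable) binning; only
  contrasts are meaningful.
* Real-data headline numbers (accuracies, F-scores, foci rates of the
  original cohort) are properties of restricted patient data; the package
  reproduces the analysis machinery and its structural behavior, not those
  numbers.
* `detect_foci()` is validated against the generator's ground truth only;
  its defaults (median + 4 robust SD, min area 3 px) are starting points
  for real images, not universal constants.
* The discriminant stage is two-class; multi-class extensions would need a
  different eigen-solution and validation design.
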