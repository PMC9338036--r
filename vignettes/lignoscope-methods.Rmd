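---
title: "Measuring and modelling the degree of cell wall lignification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling the degree of cell wall lignification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignoscope)
```

## The index and its measurement

Safranin stains lignified secondary cell walls red; Astra Blue stains
less-lignified, cellulose-rich walls blue; lumina and intercellular spaces
remain near-white. The degree of cell wall lignification of a stem
cross-section is the area fraction

$$\mathrm{DCWL} = \frac{A_{\mathrm{red}}}{A_{\mathrm{red}} + A_{\mathrm{blue}}},$$

measured by classifying every pixel of the micrograph into red, blue,
white or unclassified by thresholds on hue, saturation and brightness.
The implementation follows that measurement model exactly:

* Pixels are converted from 8-bit sRGB to HSV (`grDevices::rgb2hsv`), hue
  expressed in degrees on $[0, 360)$, saturation and value on $[0, 1]$.
  Configurations may instead be written on ImageJ's 0–255 byte scale
  (`scale: imagej`), which is converted on read.
* Classes are tested in the fixed priority red → blue → white, so a pixel
  satisfying several bands is assigned deterministically and the order is
  documented. With the default bands the classes are disjoint in practice,
  but the priority removes any ambiguity for user-supplied bands.
* The default bands — red $H \in [330,360) \cup [0,25]$, $S \ge 0.15$,
  $V \in [0.15, 0.95]$; blue $H \in [170,260]$ with the same $S$, $V$;
  white $S \le 0.10$, $V \ge 0.90$ — are separable stand-ins for the two
  stains and the bright background. They capture light-to-dark shades of
  each stain while excluding near-white and near-black pixels, and every
  value is overridable from configuration, since any particular staining
  batch or camera may need recalibrated bands.
* Unclassified pixels are excluded from both numerator and denominator:
  the index names only the red and blue wall areas. White pixels likewise
  never enter the ratio.
* An optional ROI mask excludes cracks and slide artefacts; the default
  ROI is the full frame. No morphological cleanup is applied by default —
  the measurement is a pure colour threshold.
* `normalize_white_balance()` is a software analogue of adjusting the
  camera's white balance: each channel is scaled so a user-chosen
  reference patch becomes neutral at its own brightness. A patch that is
  already neutral leaves the image untouched; black or saturated patches
  are rejected.

`compute_dcwl()` refuses to divide by zero: an image with no red or blue
pixels under the active thresholds almost always indicates a
misconfigured threshold set, and the error says so.

## The synthetic micrograph generator

Real stained sections cannot ship with the package, so validation uses a
generator with exact per-pixel ground truth. Cells are annuli — a
near-white lumen disc inside a wall ring — placed by rejection sampling
without overlap (larger cells first; a fixed attempt budget turns
infeasible packings into an error). Three cell types (wide vessels,
narrow thick-walled fibres, thin-walled parenchyma) control the lumen
radius, wall thickness and count.

Lignification is assigned per cell: each wall is entirely red with
probability equal to the target `lignified_wall_fraction` (or a per-type
override), else entirely blue, matching the visual appearance of sections
in which whole walls stain one colour. The global fraction is therefore
matched in expectation, and the ground truth `true_dcwl` is computed from
the realised label map, not the target. The per-cell draws use a shared
uniform-threshold coupling, so for a fixed seed the set of red cells grows
monotonically with the target fraction — which makes the monotonicity of
the measured DCWL testable without Monte-Carlo slack.

Rendering draws per-pixel HSV values inside the class bands (red centred
at 0°, blue at 220°, hue jitter ±10° by default; walls at
$S \in [0.65, 0.90]$, $V \in [0.45, 0.75]$; lumina and background at
$S \le 0.05$, $V \ge 0.95$), converts to 8-bit RGB, and optionally adds
Gaussian channel noise truncated to $[0, 255]$. All randomness flows from
the single seed in the spec; identical specs give bit-identical images.

What the generator does **not** emulate: growth-ring and ray geometry,
partially lignified single walls (as seen in 'Blue Rings'), staining
gradients, illumination falloff, chromatic camera noise and compression
artefacts. Passing the round-trip tests therefore shows that the
classifier is correct *given* colours inside the configured bands — it
does not show that the default bands are right for any particular real
staining protocol; those must be calibrated against inspection, which is
why the thresholds are configuration, not constants.

## The synthetic species–site study

The downstream statistics need a species table with realistic structure.
The generator emulates a global collection network with, by default,
1770 species at 198 sites spanning 40°S–80°N and sea level to 6150 m,
composed of 78.7% herbs, 16.9% trees and 4.4% shrubs, and up to ten
occurrence records per species scattered around the home site
(mean ≈ 7.4, giving ≈ 13,000 records).

Climate is a deterministic lapse-rate model plus noise:

$$T_{\mathrm{wq}} = 28 - 0.0055\,E - 0.25\,|\phi| + \varepsilon,\qquad
\varepsilon \sim N(0, 1\,^{\circ}\mathrm{C}),$$

with elevation $E$ in metres and latitude $\phi$ in degrees, so the
warmest-quarter temperature falls with elevation and latitude; the
highest, most poleward sites reach well below 0 °C. Annual precipitation
is log-normal with a latitude-dependent mean. These coefficients are
ordinary textbook magnitudes (a ~5.5 °C/km lapse, ~0.25 °C per degree of
latitude), chosen once to place the cold margin of the network below
−10 °C.

DCWL is logit-normal — normal on the logit scale, then inverse-logit —
which gives $[0, 1]$ support without clipping:

$$\mathrm{logit}(D) \sim N(\alpha_{\mathrm{lifeform}} + 0.12\,T_{\mathrm{wq}},\ \sigma_{\mathrm{lifeform}})$$

with $\alpha = -1.25$, $\sigma = 1.45$ for herbs and $\alpha = -0.15$,
$\sigma = 1.0$ for trees and shrubs. The lifeform contrast in these
defaults was calibrated by simulation so that the expected group summary
is ≈ 0.81 (SD 0.17) for trees/shrubs and ≈ 0.50 (SD 0.31) for herbs, with
binned mean DCWL rising monotonically in temperature — the qualitative
pattern the analysis stage is meant to detect: upright lifeforms always
substantially lignified, herbs spanning the whole index, and lignification
falling toward cold sites. Trees are absent from sites with
$T_{\mathrm{wq}} < 6$ °C (shrubs < 5 °C), a hard constraint emulating the
thermal limit of upright woody growth. The distributional form is a
declared modelling assumption, not a claim about real data, which the
generator cannot stand in for.

Heights are log-normal per lifeform, clamped to plausible ranges (herbs
2–200 cm, shrubs 30–500 cm, trees 200–4000 cm). Families come from a
fixed pool of 118 names with Zipf-like weights (exponent 0.8), so a
"families with more than 25 species" filter selects a meaningful handful.
Within-lifeform height has no direct effect on DCWL in the default model;
the rise of DCWL with height emerges from lifeform composition alone,
which is the dominant signal in the data the model emulates.

## Gradient statistics

* **Class binning** (`bin_means`): half-open classes
  $[o + kw, o + (k+1)w)$; a value on a boundary belongs to the
  right-hand class. Defaults per variable: 10 cm height, 1 °C
  temperature, 100 m elevation, 2° latitude, origin 0 (integer-degree
  grids for temperature and latitude follow from origin 0 with widths
  1 and 2). Empty classes are omitted, and bin counts always sum to the
  number of observations.
* **Loess** (`loess_fit`): at each evaluation point the
  $\lceil \mathrm{span}\,n \rceil$ nearest observations receive tricube
  weights $(1-(d/d_{\max})^3)^3$ and a degree-1 or degree-2 polynomial is
  fitted by weighted least squares; the fitted value is the local
  intercept. Defaults: span 0.75, degree 2, a 200-point evaluation grid.
  The curve is fitted to the class means, not the raw points — the class
  means are the published summary, and fitting to them keeps dense warm
  regions from dominating the curve. Degenerate neighbourhoods are handled
  explicitly: if all nearest neighbours coincide with the evaluation point
  the fit degenerates to their mean, and the neighbourhood is widened
  until at least degree + 1 points carry positive weight.
* **Group comparison** (`lifeform_comparison`): Welch's unpaired
  two-sample $t$ with Welch–Satterthwaite degrees of freedom, n−1 SDs and
  a two-sided p. An unpaired test is the defensible choice here because
  the two groups are different species of different counts; there is no
  pairing to exploit.
* **Percentile trimming** (`percentile_trim`): linear interpolation
  between order statistics (`stats::quantile` type 7). The convention is
  stated because percentile definitions differ; with values $1..100$ the
  2nd–98th band is $[2.98, 98.02]$, retaining $3..98$.
* **Family summaries** (`family_summary`): strict threshold (a family
  must *exceed* 25 species), statistics (median, IQR, 5th/95th
  percentiles) within trees/shrubs vs herbs.

## Redundancy analysis and variance partitioning

RDA is implemented from first principles: fit a multivariate least-squares
regression of the (column-standardised) response on the constraints with
intercept, take the fitted values $\hat Y$, and read the canonical
eigenvalues off the spectral decomposition of $\mathrm{cov}(\hat Y)$. The
constrained fraction is
$\mathrm{tr}\,\mathrm{cov}(\hat Y)/\mathrm{tr}\,\mathrm{cov}(Y)$ — for a
univariate response and one predictor this is exactly the simple-regression
$R^2$, which the tests assert to $10^{-10}$. Rank-deficient constraint
matrices are rejected with the collinear columns named. Partial RDA
residualises response and constraints on the covariates first and reports
the explained fraction on two scales: relative to the residual variance
after covariates (`constrained_fraction`, the conditional $R^2$) and
relative to the original total variance (`constrained_fraction_total`).

Variance partitioning uses the total-variance scale, on which the pieces
are additive: the unique fraction of variable $v$ is
$R^2_{\mathrm{full}} - R^2_{\mathrm{without}\,v}$, its shared fraction is
$R^2_v - \mathrm{unique}_v$, and the full-model $R^2$ equals the sum of
uniques plus a jointly shared remainder. With unadjusted $R^2$ the unique
fractions are never negative; shared fractions can be (suppression), and
are then reported as computed with a warning rather than clipped.

Significance uses reduced-model residual permutation: the response is
residualised on the covariates, its rows are permuted, and the pseudo-$F$

$$F = \frac{SS_{\mathrm{constrained}}/q}{SS_{\mathrm{residual}}/(n - q - p_{\mathrm{cov}} - 1)}$$

is recomputed per permutation. This is the standard choice for constrained
ordination when the permutation unit is the residual after nuisance
effects. The p value uses the add-one convention
$(1 + \#\{F^\ast \ge F\})/(n_{\mathrm{perm}} + 1)$, so it is never zero
and its support at 999 permutations is $\{0.001, 0.002, \ldots, 1\}$.
Under the null the p values are uniform on that support, which the test
suite checks as a type-I error rate of 0.05 ± 0.02 over 500 null
replicates. The default response in the pipeline is DCWL itself with
elevation, latitude, warmest-quarter temperature and plant height as
explanatory variables; the functions accept any response matrix, so
lifeform indicator columns or abundance matrices can be partitioned the
same way when that is the question at hand.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the
caller's RNG state. The pipeline derives per-stage seeds from one global
seed by a fixed affine map, so stages are individually re-runnable;
rerunning the pipeline with one configuration yields byte-identical
tables and summary JSON, and each output directory carries a manifest
with the seed and an MD5 hash of the configuration.

The validation suite runs on deliberately modest problem sizes chosen to
exercise every code path at high statistical resolution while staying
quick to re-run: 160 × 160 px micrographs with ≈ 85 cells (≈ 10,000 wall
pixels gives DCWL a quantisation error far below the 0.01 round-trip
tolerance), the full 1770-species study for the composition and gradient
checks, and 500 replicates × 199 permutations for the type-I calibration
of the permutation test.

## Known limitations

* Per-cell binary lignification cannot represent mixed-colour single
  walls; the ground-truth label set has no "partially lignified" class.
* The default threshold bands are placeholders for a calibrated
  supplementary threshold table; real imagery requires band calibration
  against visual inspection.
* The climate model is a one-dimensional lapse-rate abstraction — no
  continentality, aspect or snow-cover effects — and the occurrence
  scatter is isotropic, so spatial autocorrelation structure in real
  occurrence data is not emulated.
* Unadjusted $R^2$ is used throughout the partitioning; with many
  predictors and small $n$, adjusted variants would be preferable.
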