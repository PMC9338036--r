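# lignoscope

Quantifies the **degree of cell wall lignification (DCWL)** of plant stems
from double-stained cross-section micrographs, and analyses how DCWL varies
across lifeforms and climatic gradients.

## The problem

Safranin/Astra-Blue double staining colours lignified secondary cell walls
red and less-lignified (cellulose-rich) walls blue, while cell lumina and
intercellular spaces stay near-white. On a digitised cross-section the
extent of lignification can therefore be measured as an area fraction:

```
DCWL = red wall area / (red wall area + blue wall area)
```

a dimensionless index running from 0 (almost completely blue, near
un-lignified) to 1 (almost completely red, near fully lignified). Applied
to a large species collection, DCWL lets plant ecologists test whether cold
growing-season temperatures limit stem lignification — a candidate
mechanism for the thermal distribution limit of upright (tree and shrub)
growth.

The package provides the full measurement-and-analysis chain:

* **Pixel classification** (`classify_pixels`, `measure_areas`,
  `compute_dcwl`, `dcwl_from_image`): sRGB to hue/saturation/value
  conversion and threshold bands per colour class (configurable via
  YAML/JSON, on the degree scale or ImageJ's 0–255 scale), with an optional
  ROI mask and a software white-balance step
  (`normalize_white_balance`).
* **Synthetic micrographs with ground truth** (`generate_micrograph`):
  annular vessels/fibres/parenchyma rendered with known per-pixel labels
  and a known true lignified wall fraction, so the segmentation can be
  validated exactly.
* **Synthetic species–site studies** (`generate_study`): a global
  collection network (1770 species, 198 sites, ≤10 occurrence records per
  species by default) with a temperature-dependent logit-normal DCWL model
  and lifeform-specific baselines.
* **Gradient statistics** (`bin_means`, `loess_fit`, `gradient_curve`,
  `lifeform_comparison`, `pearson_correlation`, `percentile_trim`,
  `family_summary`): class-binned means (10 cm height, 1 °C temperature,
  100 m elevation, 2° latitude classes), tricube locally weighted
  polynomial curves fitted to those means, Welch group comparison and
  family summaries.
* **Variance partitioning** (`rda`, `partial_rda`, `variance_partition`,
  `permutation_test`): from-scratch redundancy analysis, partial RDA and
  unique/shared variance decomposition over elevation, latitude,
  warmest-quarter temperature and plant height, with reduced-model
  Monte-Carlo permutation tests (999 permutations by default).
* **Pipeline** (`run_pipeline`, `pipeline_config`): simulate → segment →
  assemble table → analyse → partition, with byte-reproducible outputs for
  a fixed seed. A thin CLI with the same stages ships in
  `inst/cli/lignoscope`.

## Worked example

```r
library(lignoscope)

# a synthetic stained section with 75% lignified walls, camera noise sd 8
m <- generate_micrograph(micrograph_spec(lignified_wall_fraction = 0.75,
                                         noise_sd = 8, seed = 42))
m
#> synthetic micrograph 256x256 px, true DCWL = 0.7393
dcwl_from_image(m)
#> DCWL = 0.7392  (red 8618 px, blue 3041 px, white 51103 px, other 2774 px)
```

The realised ground truth is 0.7393 (per-cell lignification makes the
realised fraction differ slightly from the 0.75 target); the
colour-threshold measurement recovers it to 4 decimal places despite the
noise.

```r
study <- generate_study(seed = 7)
lifeform_comparison(study$species)
#> group A (tree/shrub): mean 0.819, sd 0.160, n 370
#> group B (herb): mean 0.501, sd 0.319, n 1400
#> Welch t(1201.9) = 26.76, p = 3.86e-124

variance_partition(study$species$dcwl,
  study$species[, c("elevation", "latitude", "temp_warmest_quarter", "height_cm")],
  permutations = 999, seed = 7)
#> variance partitioning (total explained = 0.5071):
#>               variable marginal_fraction unique_fraction shared_fraction pseudo_F p_value
#> 1            elevation           0.36054       0.0003836         0.36015    1.374   0.262
#> 2             latitude           0.07253       0.0006477         0.07188    2.319   0.126
#> 3 temp_warmest_quarter           0.48341       0.0513148         0.43209  183.745   0.001
#> 4            height_cm           0.07424       0.0231730         0.05106   82.976   0.001
#> jointly shared (total - sum of uniques) = 0.4316
```

Upright lifeforms are strongly and consistently lignified while herbs span
the whole index; most explained DCWL variance is shared among the
collinear geographic variables, with warmest-quarter temperature carrying
by far the largest unique, significant contribution.

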