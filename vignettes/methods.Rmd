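---
title: "Methods: stand density from spectral local maxima"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stand density from spectral local maxima}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

Stand density — the number of trees per unit area (NT, reported per 400 m²
plot or per hectare) — is a basic forest-structure parameter that is
expensive to measure on the ground. At sub-metre image resolution an
individual tree crown appears as a local brightness peak: treating the
grayscale surface as terrain, each crown contributes a summit. The pipeline
in this package estimates density in four stages:

1. **Detection.** A moving-window maximum filter of size $w \times w$ pixels
   is applied to a detection band (panchromatic at 0.6 m, or NIR at 2.4 m);
   the filtered layer is subtracted from the original, and zero-difference
   pixels are the spectral local maxima (LM) — candidate crown apices.
2. **NDVI filtering.** Maxima over roads, bare soil or standing dead trees
   are pseudo crown points. NDVI $= (NIR - Red)/(NIR + Red)$ is computed on
   the multispectral grid and points whose NDVI falls below a threshold
   $t \in \{0.1, \dots, 0.5\}$ are removed.
3. **Calibration.** The surviving points are counted inside each field plot
   (the count N′, or NSLMP). For every combination of band, window size
   $w \in \{3,5,7,9,11\}$ and threshold, the Pearson correlation between N′
   and the field-measured count NT is evaluated per stratum (coniferous,
   broadleaf, and the pooled unclassified set); the maximal-r significant
   combination wins. Linear and quadratic regressions of NT on N′ are then
   fit by OLS and validated by leave-one-out cross-validation.
4. **Mapping.** Points are counted in a 20 m fishnet over the whole extent
   and the calibrated model converts cell counts to trees/ha.

The package also contains a synthetic-scene generator (`simulate_scene()`)
so that the full pipeline is testable without proprietary very-high-
resolution imagery, which cannot be redistributed.

# Detection contract

**Zero-difference rule and plateaus.** The subtract-and-threshold definition
marks *every* pixel of a flat-topped crown. To avoid systematic
overcounting, 4-connected components of equal-valued zero-difference pixels
are collapsed to one point, placed at the component pixel nearest the
component centroid (ties broken by smallest row, then column). A constant
raster therefore yields exactly one point. The exhaustive per-pixel oracle
used by the test suite applies the same collapse rule; on rasters with
all-distinct values the rule is vacuous and the match is pixel-exact.

**Borders.** The max window is clipped at the raster boundary — no padding.
Clipping is the simplest exact contract: padding with $-\infty$ would give
identical results, and reflection padding would invent data. A consequence
worth knowing: near the border a pixel's window is smaller, so border pixels
can be locally maximal with respect to fewer neighbours.

**Cross-resolution lookup.** Window sizes are in detection-band pixels, so a
3×3 window spans 1.8 m on PAN but 7.2 m on NIR. NDVI is computed on the
native 2.4 m multispectral grid and sampled by nearest neighbour (the pixel
containing the point, half-open on max edges). No pan-sharpening is
performed — fusing the bands would entangle detection and filtering
resolutions and was deliberately left out.

# Calibration choices

* **"Non-linear" model = quadratic polynomial.** The reference workflow
  reports two model degrees of freedom for its non-linear fits, which pins
  the form down to a second-order polynomial in N′; it is fit by OLS like
  the linear form.
* **RMSE uses denominator $n$** (plain root-mean-square error in trees per
  400 m² plot), not $n-k-1$.
* **LOOCV:** $r^2_{cv} = 1 - \mathrm{PRESS}/SS_{tot}$ and
  $RMSE_{cv} = \sqrt{\mathrm{PRESS}/n}$, with every held-out prediction from
  a genuine refit on the remaining $n-1$ plots.
* **Selection ranks by $r$, not $|r|$:** the count–density relationship is
  physically positive, so a strongly negative cell is a pathology, never a
  winner. If no cell is significant at $p < 0.05$ (two-tailed t on $n-2$
  df), the maximal-r cell is returned flagged non-significant.
* **Shapiro–Wilk is advisory.** The residual-normality p-value is attached
  to every model but never blocks the fit, since no rejection action is
  defined for the workflow.
* **Stratification.** The pure-stand rule is defined on stock volume in
  forest inventories; the synthetic truth has no volumes, so the tree-count
  fraction is used with the same strictly-greater-than-70 % cut. Every plot
  additionally belongs to the pooled unclassified stratum.

# The synthetic world

The generator's defaults encode the field design the pipeline targets:
73 square 400 m² plots, 26/73 coniferous-dominated; per-plot tree counts
drawn from a normal with mean 27 and SD 20 truncated to [4, 110] (the
printed mean/SD/min/max; equivalently 675, 500, 100, 2750 trees/ha);
conifer crown diameters from a normal with means 2.68 m (N–S) / 2.95 m
(E–W) and SD 0.96 m truncated to the printed range [1.38, 6.61] m;
broadleaf crowns with means 3.63/3.79 m and SD 1.52 m (no printed range;
truncated to [1, 9] m as a realistic positive support). Note that
truncating at [4, 110] raises the realized count mean to about 31.7 — the
four printed moments cannot all be matched exactly by any truncated normal;
the tests compare the sampler against its own analytic truncated moments.

Rendering mirrors the physical contrast that drives the method:

* **Conifers** are cosine-tapered radially symmetric peaks
  ($f(\rho) = \cos^2(\pi\rho/2)$ on the elliptical crown radius), so each
  crown has a single strict PAN maximum at its apex.
* **Broadleaves** are maxima of 1–3 offset Gaussian lobes with amplitude
  jitter, so a single crown can shed more than one local maximum — the
  mechanism that degrades broadleaf accuracy relative to conifers.
* **Dead trees** keep their PAN brightness but stay at background level in
  red and NIR, producing pseudo points that only NDVI filtering removes.
* **Roads** are bright strips with NDVI < 0 placed in the corridors between
  plots; **soil background** is spectrally flat (NDVI = 0).
* Reflectance constants (soil 0.06 in red/NIR, canopy NIR amplitude 0.8)
  were chosen once so that the *worst case* — a minimum-size 1.38 m crown
  whose apex falls on the corner of a 2.4 m MS pixel — still lifts that
  pixel's NDVI above the lowest threshold 0.1. Without this margin the
  separated-crown exactness property (N′ = NT) would fail for rare
  geometries, which would be an artefact of pixel alignment rather than of
  the method.
* i.i.d. Gaussian noise (default sd 0.02 reflectance, a typical sensor
  noise level) is added to the latent 0.6 m bands *before* the red/NIR
  bands are aggregated to 2.4 m as 4×4 block means, so MS noise is
  correspondingly smaller — the order the block-mean sensor model implies.

**Plot placement.** Plots sit on a 40 m slot lattice with corners at
multiples of 20 m. Two consequences: plots never overlap and are separated
by at least 20 m; and every plot coincides exactly with one cell of the
default 20 m fishnet, which turns the end-to-end map-versus-truth
comparison into an exact bookkeeping identity rather than an approximate
overlay. Within a plot, stems are uniform with a minimum-separation
rejection rule (default 1.2 m; relaxed per stem after 200 failed draws so
extreme densities remain generable) and are inset one PAN pixel (0.6 m)
from the plot boundary so a crown-apex pixel centre cannot fall on the
wrong side of the boundary. The within-plot spatial pattern of real stands
(plantation rows vs clumping) is not modelled.

**What a green test does and does not establish.** The synthetic world
validates the *mechanics* — detector exactness against an oracle,
monotonicity in window and threshold, conservation of counts, correctness
of the regression and cross-validation arithmetic, and that the grid search
recovers a well-correlated combination on scenes with known truth. It does
not establish the empirical accuracy figures of any real sensor or forest:
band ranking in particular differs (on these synthetic scenes PAN detection
usually beats NIR because 2.4 m pixels are as large as a median crown),
and real values of $r$, $R^2$ or RMSE require real imagery and field data.

# Numerical and degenerate-input conventions

* NDVI at zero denominator (NIR + Red = 0) is defined as 0.
* Point-in-polygon and point-in-cell use half-open boxes
  (`min <= x < max`), so adjacent plots and cells partition the plane and
  counts are conserved exactly.
* Pearson r is clamped to $[-1, 1]$ against rounding; $|r| = 1$ reports
  $p = 0$. Constant inputs raise an undefined-correlation error; grid cells
  with constant N′ are reported as NA and never selected.
* Ragged fishnet edge cells keep their true area; their counts are scaled
  to a 400 m² equivalent before model application. Negative model
  predictions (possible at small counts with a quadratic) are floored at 0.
* The density raster pads ragged edges out to whole 20 m pixels; the
  fishnet GeoJSON carries the exact cell geometry.
* All randomness flows from one integer seed; `generate_forest()` and
  `render_scene()` derive disjoint streams from it, so a scene is
  byte-for-byte reproducible from its parameter file.

# File formats

GeoTIFF writing is not available in this R environment (no terra/raster/sf),
so rasters use the ESRI ASCII grid (`.asc`) plain-text format, written at
full double precision for lossless round-trips; vector layers (trees, plots,
fishnet cells) are GeoJSON, tables are CSV, and configuration is JSON. The
coordinate frame is scene-local metres, x east, y north, origin at the
lower-left corner.

# Known limitations

* No radiative-transfer realism, terrain, sun/sensor geometry or
  pan-sharpening; the synthetic scenes are a statistical, not physical,
  emulation.
* The detector cannot separate crowns closer than one window radius, and
  the method saturates at high density — the regression absorbs some of
  this, the quadratic term in particular.
* Stratum-specific mapping requires an external stratum mask per cell; with
  none supplied the pooled (unclassified) model is applied everywhere.
* On real data the observation table is taken as given; no rule is applied
  for removing plots before regression.
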