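---
title: "Counting cyanobacteria by fluorescence-contrast image analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cyanobacteria by fluorescence-contrast image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanocount)
```

## The problem and the imaging model

Routine monitoring of cyanobacteria in source waters asks for cell
concentrations (cells/ml) of taxa such as *Microcystis aeruginosa*
(unicellular, near-spherical) and *Anabaena flos-aquae* (filamentous
chains), counted quickly enough to be practical and robustly enough to
survive a real water matrix. When the natural photosynthetic pigments
(chlorophyll-a, phycocyanin) are excited at a suitable wavelength the
cells fluoresce against an almost dark background, so a hemocytometer
field imaged under fluorescence reduces to a tractable computer-vision
problem: bright, compact or elongated objects on a dark, noisy
background. `cyanocount` implements that reduction as a two-phase
pipeline. The fluorescence signature is used *only* for contrast; all
identification is morphological.

**Phase 1 (calibration).** Sonicated, size-filtered preparations leave
well-isolated single cells. Segmenting those images and averaging the
component areas yields the *unit-cell projected area* (um^2 per cell)
for each species, with its SD ([`calibrate_unit_area()`]).

**Phase 2 (enumeration).** Each field is segmented, connected components
are measured and classified, and counts become concentrations:

* unicellular classes: one component = one cell, so components are
  counted ([`enumerate_unicellular()`]);
* the filamentous class: a filament is one component of many cells, so
  the estimated cell number is the total class area divided by the
  Phase-1 unit-cell area ([`enumerate_filamentous()`]). This quotient is
  deliberately reported as a real number; rounding happens only in
  display.

## Pixel classification

Each pixel is classified foreground/background by a learned intensity
threshold: a pixel with intensity `f >= theta` is foreground (the
boundary value is inclusive). `theta` is chosen to maximize the
between-class variance of the split — the classical Otsu criterion —
which assumes nothing about the intensity distribution of either class
(`learn_threshold()`). The search runs over every native gray level for
8-bit data; deeper (12/16-bit) images are binned to 256 equal-width bins
and the winning bin's lower edge is mapped back to the native scale,
which avoids the instability of nearly-empty sparse histograms. Ties in
the objective (common when the two modes are separated by empty bins)
resolve deterministically to the lowest maximizing threshold. A constant
training region is rejected as degenerate: no split exists. The
training region defaults to the whole image and can be restricted to a
rectangle when a sub-field is more representative.

The test suite pins this implementation to an exhaustive oracle that
recomputes the objective from the raw pixels for every candidate
threshold on 100 seeded random images, including the tie-break.

## Components and the seven descriptors

Foreground pixels are grouped into connected components, by default
under 8-neighbour adjacency so that diagonally touching filament
segments remain one object; components smaller than
`min_component_area_px` (default 4 px) are discarded as shot noise, and
labels are assigned in raster-scan order of each component's first pixel
so labelling is reproducible. Per component, `featurize()` reports:

| descriptor | definition | notes |
|---|---|---|
| area `A` | pixel count | `area_um2 = A * um_per_pixel^2` |
| perimeter `P` | chain-code length of the traced outer boundary | axial steps 1, diagonal steps sqrt(2) |
| eccentricity `e` | focal distance / major axis of the moment-fitted ellipse | 0 for a circle, 1 for a segment |
| compactness `c` | `4*pi*A/P^2` | 1 for an ideal circle |
| convex area | area of the convex hull | hull over pixel *corner* points |
| solidity | `A` / convex area | <= 1 by construction |
| extent | `A` / bounding-box area | <= 1 |

Numerical choices worth knowing:

* **Perimeter.** The boundary is traced with a Moore-neighbour contour
  follower (Jacob's stopping criterion, so pinched shapes terminate
  correctly) and measured as the (1, sqrt(2))-weighted chain length. We
  compared this against corrected chain-code weightings
  (0.948/1.340-type schemes) on discs and ellipses spanning the cell
  size range: the corrected weights are better for large smooth discs
  (-0.5% vs +4.6% at radius 20 px) but degrade to -8% on cell-sized
  ellipses (~5 x 4 px semi-axes), while the plain weighting stays
  within about +/-5% everywhere in the range that matters here. For
  objects only a few pixels across no chain estimator is reliable:
  discretization can push `c` above its theoretical bound of 1, which
  is why measured compactness values up to ~1.3 for 4-px-radius cells
  are reported unclipped with a warning rather than truncated —
  truncation would destroy the contrast between compact unicells and
  sprawling filaments that the classifier uses.
* **Eccentricity** comes from the second central moments of the pixel
  centres; a disc rasterized about a pixel centre is exactly isotropic,
  so its eccentricity is exactly 0, and a 1-px line has exactly 1. A
  single-pixel component is defined to have eccentricity 0 and
  perimeter 1 (such components are normally removed by the area filter).
* **Convex hull on pixel corners.** Treating each pixel as a unit
  square and hulling the corner points guarantees the hull contains the
  full pixel area, so solidity never exceeds 1 — hulling pixel centres
  would not.

## Component classification

**Two-species rule cascade** (`classify_rule()`). With thresholds
`omega` (eccentricity), `tau` (compactness) and per-species area windows
`[psi_al, psi_au]`, `[psi_ml, psi_mu]`:

* filamentous `C_A` iff `e >= omega` and `c <= tau` and the area lies in
  the filament window;
* unicellular `C_M` iff `e < omega` and `c > tau` and the area lies in
  the single-cell window;
* `C_N` (neither) otherwise.

The branches are disjoint by construction (`e >= omega` vs `e < omega`),
so every component receives exactly one label. The boundary operators
are implemented exactly as written: equality on `omega`/`tau` belongs
to the filamentous branch.

Defaults `omega = 0.70`, `tau = 0.80` are midpoints between
representative pure-culture values of the two taxa (eccentricity 0.85
vs 0.52, compactness 0.64 vs 0.98). The area windows were an open
design point: the natural reading — a window around one unit-cell area
— is right for the unicellular class (default 0.25x to 4x the
calibrated unit area) but cannot work for filaments, whose components
span tens of unit cells. `rule_thresholds_from_calibration()` therefore
widens the filament window to 0.5x–200x the unit-cell area by default:
the lower edge still admits single sonicated fragments while the upper
edge admits ~200-cell chains, beyond which entangled mats should be
rejected to `C_N` rather than divided into implausible counts.

**Three-species SVM** (`train_svm()`, `cross_validate()`). When the
needle/spindle-shaped green alga *Ankistrodesmus* (`C_K`) is present it
overlaps the filament class in any single feature, so a quadratic
(degree-2 polynomial) kernel SVM over all seven descriptors is used
instead. Features are z-scored before kernel evaluation (the scaling is
stored in the model); the multi-class reduction is one-vs-one; the
soft-margin constant defaults to 1 and the kernel offset to 1, so the
kernel contains the linear terms. Cross-validation is stratified
per class and fully seeded. None of these four choices (scaling, C,
offset, reduction) is forced by the problem; they are the conventional
defaults and are recorded with the model so runs are reproducible.

**Evaluation** (`classification_metrics()`). One-vs-rest reduction to
TP/TN/FP/FN gives specificity `TN/(TN+FP)`, sensitivity = recall
`TP/(TP+FN)`, accuracy, precision `TP/(TP+FP)` and F1. Sensitivity is
implemented in its standard form (identical to recall). Ratios with a
zero denominator are reported as `NA` with a warning — never silently
as 0, which would poison averages.

## From counts to concentrations

A hemocytometer field images a fixed volume: grid area x chamber depth.
Defaults are a 1 mm^2 grid at 0.1 mm depth (0.1 uL per field, the
standard improved-Neubauer geometry); both are configuration values, as
is the sample dilution factor. `to_concentration()` divides the mean
per-image cell estimate by that volume (1 um^3 = 1e-12 ml) and scales
by the dilution. The micrometres-per-pixel calibration has *no*
default anywhere in the pipeline — it depends on the objective and
sensor and silently wrong area units would corrupt every filament
count. The synthetic generator uses 0.645 um/px, i.e. a 6.45 um sensor
pixel behind a 10X objective, as a realistic value. Replicate
variability is reported as the SD of per-image estimates, the way
replicate hemocytometer fields are reported in practice. Objects are
counted wherever segmented; no border-exclusion rule is applied beyond
the raster boundary itself.

## The synthetic-data generator

`generate_scene()` renders ground-truthed scenes: 12-bit 1200 x 1600
rasters (the camera format this pipeline targets) with

* discs with radius ~ N(2.80, 0.19) um — projected areas ~ N(24.6, 3.4)
  um^2, matching calibrated unicell magnitudes;
* filaments as chains of elliptical cells (6.83 x 5.0 um, ~26.8 um^2
  per cell) with a random-walk heading (SD 0.15 rad/cell) and 10%
  inter-cell overlap so each chain is one connected component whose
  true cell count is recorded;
* spindles as thin ellipses (40 +/- 10 um long, 2.5 um wide);
* intensities: background N(150, 40), cells N(1800, 150) per object
  plus N(0, 40) per pixel, clipped to the bit depth — additive Gaussian
  noise only, no Poisson shot-noise or PSF model;
* optional multiplicative illumination ramp and star-polygon debris
  (recorded in the ground truth, never in class totals) to emulate a
  lake-water matrix.

Placement is rejection-sampled; by default objects are disjoint with a
2 px margin, and an unplaceably dense request fails loudly naming the
class. Everything is seeded: the same spec renders bit-identical
scenes. `generate_dilution_series()` derives per-level seeds and draws
realized counts from a Poisson law around `base_counts / factor`,
mirroring serial dilution of a suspension.

What passing synthetic tests does *not* show: real micrographs have
out-of-focus filament segments, touching and overlapping cells beyond
what sonication removes, autofluorescence bleed, and debris
distributions unlike star polygons. Overlapping objects merge into one
component here by design (the protocol relies on sonication to break
aggregates), so aggregation biases counts downward on real data; the
filament area-division estimator carries a small (~3%) downward bias
from inter-cell overlap in the synthetic chains themselves, well inside
its 10% validation band.

## Validation problem sizes

The shipped validation experiments (the package test-suite and
`scripts/acceptance.R`) use: 100 random 64 x 64 images for the
threshold oracle; full-frame (1200 x 1600) scenes with 10–200 discs for
count recovery; a five-level dilution series (factors 1, 2, 10, 500,
1000 — i.e. relative densities 1 to 0.001) with 5 images per level for
linearity (R^2 >= 0.98, slope within [0.9, 1.1]); six two-species
mixtures from 100% to 0% filaments recovered within 5 percentage
points; a 272-per-class Gaussian feature benchmark (816 rows) for the
SVM, on which five-fold CV reaches >= 95% accuracy and collapses to
~1/3 under label permutation; and 100-cell calibration populations
recovered within two standard errors. These sizes were chosen so the
full suite runs in a few minutes on one core while keeping each
estimate's sampling error well below the tolerance it is tested
against.

## Known limitations

* Counts are per connected component: colonies or entangled filaments
  that survive sample preparation are undercounted.
* The unit-cell calibration excludes elongated components
  (eccentricity above `omega` by default) as residual fragments; with a
  badly prepared sample this gate can bias the retained set.
* Sub-cellular resolution is assumed (several pixels across a cell);
  at coarser sampling the perimeter/compactness discretization bias
  grows quickly.
* The rule cascade is only as good as its thresholds; they are
  empirical and should be re-derived (via `calibrate_unit_area()` and
  inspection of feature distributions) for new optics or taxa.
* Biovolume (idealized 3-D geometry) and any use of spectral
  information for classification are out of scope.
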