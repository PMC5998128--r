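# cyanocount

Automated identification, differentiation and enumeration of
cyanobacterial and algal cells in fluorescence micrographs.

Harmful-algae monitoring needs cell concentrations (cells/ml) of taxa
such as *Microcystis aeruginosa* (unicellular, near-spherical) and
*Anabaena flos-aquae* (filamentous), but manual hemocytometer counts are
slow and imprecise at low densities. Under excitation of their natural
pigments the cells fluoresce against a dark background, which turns each
hemocytometer field into a bright-objects-on-dark segmentation problem.
`cyanocount` implements the full two-phase analysis for water-quality
labs and method developers:

1. **Pixel classification.** A threshold θ is learned per image by
   maximizing the between-class variance of the foreground/background
   split (Otsu's criterion; no distributional assumption); pixels with
   f(x) ≥ θ are foreground.
2. **Components and morphology.** Connected components (8-adjacency,
   minimum-area filtered) are measured by seven descriptors: area A,
   perimeter P, eccentricity ε (moment-fitted ellipse), compactness
   c = 4πA/P², convex area, solidity and extent.
3. **Classification.** A rule cascade assigns a component to the
   filamentous class C_A iff ε ≥ ω ∧ c ≤ τ ∧ ψ_AL ≤ A ≤ ψ_AU, to the
   unicellular class C_M iff ε < ω ∧ c > τ ∧ ψ_ML ≤ A ≤ ψ_MU, else to
   C_N. With a third, morphologically similar taxon
   (*Ankistrodesmus*, C_K) a quadratic-kernel SVM over all seven
   features replaces the rule, evaluated by stratified five-fold
   cross-validation and confusion-matrix metrics (specificity,
   sensitivity/recall, precision, accuracy, F1).
4. **Enumeration.** Unicellular classes are counted per component;
   filament cell numbers are total class area ÷ the Phase-1 calibrated
   unit-cell area; counts convert to cells/ml via the chamber geometry
   (grid area × depth × dilution).

A fully seeded synthetic micrograph generator (discs, filament chains
with per-cell ground truth, spindles, debris, illumination gradients)
makes every stage testable without microscope data.

## Worked example

```r
library(cyanocount)
cfg <- run_config(um_per_pixel = 0.645, dilution_factor = 1)

## Phase 1: calibrate the unit-cell area from single-cell preparations
cal_imgs <- lapply(1:2, function(i) generate_scene(scene_spec(
  image_size = c(600, 800), counts = c(C_A = 40),
  filament = list(cells_mean = 1, cells_sd = 0, cell_length_um = 6.83,
                  width_um = 5.0, curvature = 0, overlap_frac = 0.1),
  seed = 100 + i))$image)
cal <- calibrate_unit_area(cal_imgs, "C_A", cfg, max_eccentricity = 0.85)
cal
#> <calibration_model> C_A: 26.8 +/- 0.603 um^2 (n = 80)

## Phase 2: enumerate a mixed two-species field
scene <- generate_scene(scene_spec(counts = c(C_M = 60, C_A = 8), seed = 42))
scene$truth
#> <ground_truth> 68 object(s); cells: C_M=60 C_A=91 C_K=0

report <- run_pipeline(list(scene$image), cfg, calibration = cal)
report
#> <enumeration_report> 1 image(s)
#>  class object_count total_area_um2 estimated_cells cells_per_ml sd
#>    C_A            7       2327.244              87     867454.9  0
#>    C_M           60       1471.896              60     600000.0  0
round(report$proportions, 3)
#>   C_A   C_M
#> 0.591 0.409
```

Reading the output: all 60 unicells are recovered exactly by component
counting. The 8 filaments (91 true cells) segment into 7 components —
two passed close enough to merge — but because filament cells are
estimated from *total area*, not component count, the estimate is 87
cells (−4%). At 0.1 µL per field (1 mm² grid × 0.1 mm depth), 60 cells
per image is 6.0 × 10⁵ cells/ml. The recovered mixture proportion
(59.1% filamentous) sits 1.2 points from the ground truth (60.3%).

Real images enter through `read_image()` (8/12/16-bit TIFF/PNG; 12-bit
acquisitions inside 16-bit containers are auto-detected) with the
µm/pixel calibration of your optics, and a flat key=value config file
(`read_config()`) carries chamber geometry and rule thresholds. A thin
command-line front end with `segment`, `features`, `classify`,
`calibrate`, `enumerate`, `synth` and `pipeline` subcommands is
installed at `inst/cli/cyanocount.R`.

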