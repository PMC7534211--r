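---
title: "Methods: shear-stress design and per-cell actin-texture quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shear-stress design and per-cell actin-texture quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

This vignette is the package's own account of its models, parameter
choices, and the reasoning behind the open design decisions. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. Shear-stress design

Two perfusion geometries are supported, both under fully developed,
laminar, Newtonian flow.

**Cylindrical capillary.** Wall shear stress follows the Hagen–Poiseuille
relation τ = 32 Q µ / (π d³), with d the inner diameter. The reference
device is a 560 µm / 80 mm borosilicate capillary whose bore mimics
trabecular-bone pore dimensions.

**Parallel-plate flow chamber.** For a wide, shallow rectangular channel
(width w, height h, h ≪ w) the plane-Poiseuille wall shear is
τ = 6 Q µ / (w h²). The reference chamber is 5 mm × 200 µm × 50 mm. The
formula neglects side-wall effects, so `chamber_geometry()` warns when
h/w > 0.2. The two formulas are mutually consistent at the reference
operating points: 10 µl/min in the capillary gives 9.67 mPa and 20 µl/min
in the chamber gives exactly 10.0 mPa — within 4% of each other and both
10 mPa to the nearest mPa.

**Fluid properties.** The medium viscosity behind the published 10 mPa
figure is not stated anywhere we could find; we assume µ = 1.0 mPa·s and
ρ = 1000 kg/m³ (culture medium at 37 °C) and expose both as arguments.
The Reynolds number (mean velocity, tube diameter or hydraulic diameter)
is reported with every calculation; Re ≥ 2000 warns rather than errors,
since the formula degrades gracefully and the bench regimes of interest
sit at Re < 1.

Internally everything is strict SI (m, Pa·s, m³/s, Pa); the converters
`ul_min_to_m3s()`, `m3s_to_ul_min()`, `pa_to_mpa()`, `mpa_to_pa()` and the
CLI handle bench units explicitly to prevent magnitude errors.

## 2. The synthetic-image generator

No public raw data exist for this kind of experiment, so the generator is
the package's test bed: every downstream stage is validated against its
exact ground truth.

A scene is a three-channel z-stack (DAPI, phalloidin, nuclear marker) of
`n_cells` elliptical cells placed by rejection sampling under
centre-separation and border constraints (bounded retries, default 1000;
failure is an explicit placement error). Defaults follow the reference
acquisition: 1024 × 1024 px, ≥ 20 planes, 10× objective (1.14 µm pixels).
Each cell's signal is spread over z with a Gaussian axial profile peaking
at 1 on its centre plane, so the maximum-intensity projection recovers the
in-focus image and is a meaningful, testable step.

**Channels.** DAPI and the nuclear marker fill the nucleus ellipse; the
per-cell marker intensity is drawn from the group's
N(`runx2_mean`, `runx2_sd`) and rounded to the stored grid, and the ground
truth records the *rendered* value, so noiseless recovery can be asserted
exactly.

**Actin phenotypes.** Two cytoskeletal organisations are rendered in the
phalloidin channel, both over a faint diffuse cortical mesh and both
rescaled so the whole-cell mean intensity is exactly the scene's
`actin_mean` — the matched-mean contract that guarantees downstream texture
differences are not brightness differences:

* *homogeneous_filaments* — many thin, roughly aligned chords with a
  Gaussian cross-profile spread over the whole cytoplasm;
* *peripheral_stress_fibres* — a few thick, bright arcs confined to the
  outer annulus (`peripheral_band_fraction` of the radius), individual
  fibres varying in brightness and calibre, over a dimmer interior.

The source literature describes these phenotypes only qualitatively, so the
quantitative defaults are the package's own: 80 filaments of ~2 px at 0.4×
relative amplitude for the homogeneous kind, 7 fibres of ~5 px at 10×
relative amplitude for the peripheral kind. They encode two physical
judgements: at a 10× objective (~1.1 µm pixels) thin actin bundles sit at
the resolution limit and merge into a near-uniform fine mesh, while
peripheral stress fibres are micrometres thick and markedly brighter. The
scale of the contrast between the phenotypes was calibrated so that the
synthetic experiment reproduces the qualitative outcome reported for the
real one — a group difference detectable at n = 6 samples — since a
generator whose phenotypes were indistinguishable at the study's sample
size would not emulate the study. Both phenotypes remain configurable
per group.

**Noise.** Per plane: scaled Poisson shot noise on (signal + background)
with `poisson_scale` photons per intensity unit, additive Gaussian read
noise, then clipping and rounding at the stored bit depth (default
16-bit). Defaults (0.5, sd 20, background 100) give a per-pixel noise sd
of ~70–90 intensity units at typical signal levels — a visibly noisy but
easily segmentable confocal image. `noise = NULL` yields the exact
noiseless render.

**Determinism.** A scene is a pure function of (spec, seed): placement,
phenotype rendering, intensity draws and noise all consume the single R
RNG stream after one `set.seed()`. The generator uses no FFT or
platform-dependent numerics.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: optical PSF and depth-dependent blur, spectral
bleed-through, photobleaching, autofluorescence, uneven illumination,
cell-shape irregularity beyond ellipses, and 3-D filament structure.
Phenotypes are specified in 2-D projection terms because the analysis
operates on projections.

## 3. Projection, segmentation, and quality control

The preprocessing mirrors the standard confocal workflow: per-pixel
maximum-intensity projection (checked to dominate every plane pointwise
and to be idempotent), then a channel split into DAPI / phalloidin /
marker images.

**Nuclei.** Gaussian smoothing (σ = 2 px) → global Otsu threshold →
connected components → distance-transform watershed declumping
(tolerance 2) → speck removal. A fixed numeric threshold can replace Otsu
for noiseless fixtures. Blank or constant images return an empty mask with
a warning, not an error. Labels are always renumbered in centroid
(row, col) order, making segmentation deterministic including tie-breaks.

**Isolated-cell QC.** The reference workflow removed overlapping and
bordered cells by hand; manual curation cannot be tested, so the exclusion
is automated with four explicit rules, each recorded per candidate in a QC
report: touching the image border; area outside [80, 2500] px (at ~1.1 µm
pixels, nuclei far smaller or larger than plausible); solidity < 0.85
(merged or mis-segmented shapes); and any object whose mask lies within
r_touch = 3 px of another (both members of the pair are dropped).

**Cytoplasm.** Foreground is the smoothed phalloidin image above a global
Otsu threshold; each foreground pixel is assigned to a nucleus by
intensity-weighted propagation (the CellProfiler-style secondary-object
strategy, EBImage's `propagate`), with λ = 1e-4 trading intensity- against
distance-dominance. Cytoplasm label k always contains nucleus k (asserted
after every propagation); foreground unreachable from any seed stays
background; a nucleus with no surrounding foreground keeps its own region
with a warning.

A deliberate property of this design, inherited from the workflow it
reproduces: the measured "cytoplasm" is the *actin-positive* region. For a
stress-fibre cell with a dim interior, the identified region concentrates
on the bright fibres. The texture contrast between phenotypes measured by
the full pipeline therefore reflects the measurement process as well as
the raw texture — with ground-truth masks substituted for segmentation,
the ordering of the two phenotypes can differ. This is not an artifact to
remove but a faithful reproduction of how texture is measured "at the
identified cytoplasm" in practice; it is why the package's
phenotype-separation checks run through `quantify_stack()` rather than
through ground-truth masks.

## 4. Per-cell measurement

Nuclear marker intensity is the mean over nucleus pixels of the marker
channel; because mean vs integrated intensity is ambiguous in the
workflow being reproduced, the integrated (summed) intensity is emitted as
a secondary column.

Texture uses the grey-level co-occurrence matrix of the cytoplasm region
of the phalloidin image. Choices, all recorded in the output metadata:

* **Quantization**: per-object min–max rescaling into g = 8 levels
  (`floor((v - min)/(max - min) · g)`, capped at g − 1; constant regions
  map to level 0). Per-object quantization makes contrast and entropy
  invariant to affine intensity rescaling — illumination robustness —
  at the cost of comparability of absolute grey levels between cells; an
  image-wide mode exists to probe that sensitivity.
* **Offsets**: distance d = 3 px in the four standard directions (0°,
  45°, 90°, 135°), each GLCM symmetric, features averaged over directions
  with per-direction values also emitted. The co-occurrence distance used
  in the original analyses is unknown; d = 3 at 8 levels mirrors common
  defaults of the analysis software this pipeline follows.
* **Features**: contrast Σ(i−j)²p(i,j) (bounded by (g−1)²) and entropy
  −Σ p log₂ p in bits (bounded by 2 log₂ g). Degenerate regions (no
  admissible pixel pair in any direction) are flagged, not fabricated:
  the cell's texture is NA and `qc_texture_degenerate` is set.

Both features are verified against exhaustive pair enumeration (all 512
binary 3×3 images, exact) and against an independent reference
implementation (scikit-image co-occurrence matrices with per-angle
distances matched to the chessboard offsets) to 1e-6.

## 5. Group statistics

The experimental design is 2 geometries × 2 flow conditions with n = 6
independent samples per group. Cells within one tube or chamber share a
micro-environment, so the **sample is the replication unit**: per-cell
measurements are averaged within sample before testing. A per-cell mode
exists but labels its output as pseudo-replication. Donor is pooled, not
modelled as a factor — matching the design being reproduced; a
donor-blocked analysis is out of scope.

Per measure (marker mean, contrast, entropy): classical one-way ANOVA
(between/within mean squares, (k−1, N−k) df) followed by Tukey HSD with
the Tukey–Kramer extension for unbalanced groups, α = 0.05. Degenerate
dispersion is handled explicitly before the linear-model fit: identical
observations give F = 0, p = 1 (and all adjusted p = 1) rather than
floating-point noise; zero within-group variance with distinct means gives
an exact separation. A Brown–Forsythe check logs a warning when group
variances look heterogeneous; no further diagnostics are attempted. The
comparison report highlights the design's planned
contrasts — geometry at matched flow (`#`) and flow within geometry
(`*`).

Validation: F agrees with a hand-computed sum-of-squares fixture to
1e-10 and equals the squared pooled t statistic for two groups; Tukey
p-values match a first-principles studentized-range (ptukey) oracle to
1e-6; the all-null hierarchical experiment holds the empirical type-I rate
near α; and a perfused-capillary shift of twice the generator's within-
group (per-cell) sd is detected at n = 6 in well over 80% of seeds. The
power simulation uses the hierarchical measurement model (cells averaged
within samples) because that is the quantity the pipeline actually tests.

## 6. Pipeline, configuration, and reproducibility

`run_experiment()` drives simulate → quantify → compare for all four
groups from one nested configuration (YAML-serialisable; explicit base
seed; per-scene seeds derived arithmetically from it). Outputs are
per-cell and per-sample CSVs with self-describing metadata headers, ANOVA
and Tukey tables, the device design report, and a manifest carrying an
MD5 config hash, package version, file list and collected warnings. Two
runs of the same config are bit-identical in stacks and per-cell tables.
The CLI (`inst/cli/perfusim`) is a thin wrapper over these functions.

## 7. Problem sizes used by the test suite

The package defaults describe full-scale acquisition (1024 × 1024 × 20
planes). The test and acceptance suites exercise the identical code paths
at reduced field sizes chosen as the smallest that keep every geometric
constraint comfortable: 256 × 256 px, 5 planes, 6 cells per field for
pipeline and phenotype checks (36 cells per phenotype for the separation
test); 512 × 512 noiseless fields for the 1–20-cell segmentation-recovery
sweep; 192 × 192, 3 planes for determinism round trips; 1000 seeds for the
type-I simulation and 200 for power. These sizes are stated here as the
package's documented test conditions.

## 8. Known limitations

* The shear formulas ignore entrance length and developing flow;
  non-Newtonian rheology (relevant for cell suspensions or blood
  analogues) is explicitly out of scope.
* Segmentation is 2-D, classical, and threshold-based; densely packed or
  highly irregular cells will be excluded by QC rather than resolved.
* Texture is limited to the two Haralick features the reproduced workflow
  used; the other classic features and multi-scale texture are non-goals.
* The synthetic phenotype parameters are package choices, not published
  measurements; conclusions about real images require the caveats in
  section 2.
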