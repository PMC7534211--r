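Package: perfusim
Title: Shear-Stress Design and Per-Cell Actin-Texture Quantification for
    Biomimetic Perfusion Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing low-shear perfusion
    experiments on adherent cells. Computes laminar wall shear stress and
    required flow rates for cylindrical capillary tubes (Hagen-Poiseuille)
    and parallel-plate flow chambers (plane Poiseuille), simulates
    multichannel confocal-like z-stacks with known ground truth (elliptical
    nuclei, two actin cytoskeleton phenotypes, nuclear marker intensity,
    Poisson-Gaussian noise), segments nuclei and cytoplasm from maximum
    intensity projections with automated quality-control exclusion of
    bordered and touching cells, measures per-cell nuclear marker intensity
    and grey-level co-occurrence (Haralick) contrast and entropy of the
    actin channel, and compares experimental groups with one-way ANOVA and
    Tukey post hoc tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tools,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
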