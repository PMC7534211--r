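test_that("scene generation is deterministic and respects placement rules", {
  spec <- small_scene_spec(n_cells = 5L, seed = 33L)
  sc1 <- generate_scene(spec)
  sc2 <- generate_scene(spec)
  expect_identical(sc1$stack$dapi, sc2$stack$dapi)
  expect_identical(sc1$stack$phalloidin, sc2$stack$phalloidin)
  expect_identical(sc1$stack$runx2, sc2$stack$runx2)
  expect_identical(sc1$truth$cells, sc2$truth$cells)

  expect_equal(nrow(sc1$truth$cells), 5)
  nm <- sc1$truth$nucleus_mask
  cm <- sc1$truth$cytoplasm_mask
  expect_setequal(setdiff(unique(as.vector(nm)), 0), 1:5)
  # interior: no cytoplasm pixel on the border (allow_border_cells = FALSE)
  expect_true(all(cm[1, ] == 0) && all(cm[nrow(cm), ] == 0) &&
                all(cm[, 1] == 0) && all(cm[, ncol(cm)] == 0))
  # nuclei nested in their own cytoplasm, masks disjoint across cells
  expect_true(all(cm[nm > 0] == nm[nm > 0]))
})

test_that("an empty scene is pure background and infeasible packing errors", {
  sc <- generate_scene(small_scene_spec(n_cells = 0L, noise = NULL))
  expect_equal(nrow(sc$truth$cells), 0)
  expect_true(all(sc$stack$dapi == 0))
  expect_true(all(sc$stack$runx2 == 0))

  expect_error(
    generate_scene(small_scene_spec(image_size = c(128L, 128L),
                                    n_cells = 30L)),
    "placement error")
})

test_that("noiseless nuclear marker equals the drawn ground-truth value", {
  sc <- generate_scene(small_scene_spec(n_cells = 4L, noise = NULL,
                                        seed = 5L))
  proj <- max_intensity_projection(sc$stack)
  for (k in sc$truth$cells$cell_id) {
    nm <- sc$truth$nucleus_mask == k
    expect_equal(mean(proj$channels$runx2[nm]),
                 sc$truth$cells$runx2_true_mean[
                   sc$truth$cells$cell_id == k])
  }
})

test_that("phenotypes are rendered at matched mean but different dispersion", {
  cell <- list(centre = c(40, 40), semi_axes = c(28, 22), theta = 0.4)
  rows <- 1:80; cols <- 1:80
  set.seed(7)
  hom <- render_phenotype(cell, phenotype_spec("homogeneous_filaments"),
                          rows, cols)
  per <- render_phenotype(cell, phenotype_spec("peripheral_stress_fibres"),
                          rows, cols)
  inside <- hom > 0 | per > 0
  # matched whole-cell mean (exact by construction, < 2% required)
  expect_equal(mean(hom[hom > 0]), 1, tolerance = 1e-10)
  expect_equal(mean(per[per > 0]), 1, tolerance = 1e-10)
  # peripheral organisation concentrates intensity: higher pixel variance
  expect_gt(var(per[per > 0]), var(hom[hom > 0]))
})

test_that("stress fibres live in the outer annulus, filaments everywhere", {
  cell <- list(centre = c(45, 45), semi_axes = c(30, 30), theta = 0)
  rows <- 1:90; cols <- 1:90
  rho <- sqrt(outer((rows - 45)^2, rep(1, 90)) +
                outer(rep(1, 90), (cols - 45)^2)) / 30
  set.seed(8)
  per <- render_phenotype(cell,
                          phenotype_spec("peripheral_stress_fibres",
                                         peripheral_band_fraction = 0.25),
                          rows, cols)
  set.seed(8)
  hom <- render_phenotype(cell, phenotype_spec("homogeneous_filaments"),
                          rows, cols)
  outer_band <- rho > 0.75 & rho <= 1
  interior <- rho <= 0.75
  # intensity mass above the diffuse floor concentrates in the band
  excess_per <- pmax(per - stats::median(per[per > 0]), 0)
  frac_band <- sum(excess_per[outer_band]) / sum(excess_per)
  expect_gt(frac_band, 0.6)
  # the homogeneous phenotype keeps its interior brighter than the
  # peripheral phenotype's interior at matched whole-cell mean
  expect_gt(mean(hom[interior & hom > 0]), mean(per[interior & per > 0]))
})

test_that("aligned filaments at zero dispersion share one orientation", {
  cell <- list(centre = c(45, 45), semi_axes = c(30, 30), theta = 0)
  rows <- 1:90; cols <- 1:90
  coherence <- function(layer) {
    gx <- layer[, -1] - layer[, -ncol(layer)]
    gy <- layer[-1, ] - layer[-nrow(layer), ]
    n <- min(nrow(gx), nrow(gy)); m <- min(ncol(gx), ncol(gy))
    gx <- gx[1:n, 1:m]; gy <- gy[1:n, 1:m]
    jxx <- sum(gx^2); jyy <- sum(gy^2); jxy <- sum(gx * gy)
    sqrt((jxx - jyy)^2 + 4 * jxy^2) / (jxx + jyy)
  }
  # bright thin filaments so the (isotropic) cell-boundary edge does not
  # dominate the gradient field
  set.seed(21)
  aligned <- render_phenotype(
    cell, phenotype_spec("homogeneous_filaments", filament_count = 40,
                         filament_thickness = 1, filament_intensity = 3,
                         orientation_dispersion = 0), rows, cols)
  set.seed(21)
  spread <- render_phenotype(
    cell, phenotype_spec("homogeneous_filaments", filament_count = 40,
                         filament_thickness = 1, filament_intensity = 3,
                         orientation_dispersion = 60), rows, cols)
  # structure-tensor coherence: 1 = single orientation, 0 = isotropic
  # (the cell-boundary edge contributes an isotropic floor)
  expect_gt(coherence(aligned), 0.8)
  expect_lt(coherence(spread), coherence(aligned) - 0.2)
})

test_that("phenotype and scene specifications validate their inputs", {
  expect_error(phenotype_spec(filament_count = 0), "filament_count")
  expect_error(phenotype_spec(filament_thickness = 0.2), "thickness")
  expect_error(phenotype_spec(peripheral_band_fraction = 0), "band_fraction")
  expect_error(scene_spec(n_cells = -1))
  expect_error(scene_spec(nucleus_radius_range = c(30, 40),
                          cell_radius_range = c(20, 25)))
})
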