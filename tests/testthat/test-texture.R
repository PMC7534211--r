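test_that("masked quantization follows the min-max binning formula", {
  full <- matrix(TRUE, 4, 4)
  # constant region: all level 0
  q <- quantize_masked(matrix(7, 4, 4), full, g = 8)
  expect_true(all(q == 0))
  # exactly g equally spaced values map bijectively onto 0..g-1
  m <- matrix(rep(c(0, 10, 20, 30), each = 4), 4, 4, byrow = TRUE)
  q <- quantize_masked(m, full, g = 4)
  expect_identical(sort(unique(as.vector(q))), 0:3)
  expect_true(all(q[m == 10] == 1))
  # 4x4 ramp vs the direct formula
  ramp <- matrix(1:16, 4, 4)
  q <- quantize_masked(ramp, full, g = 4)
  ref <- pmin(floor((ramp - 1) / (16 - 1) * 4), 3)
  expect_true(all(q == ref))
  # empty mask refused
  expect_error(quantize_masked(ramp, matrix(FALSE, 4, 4)), "empty-region")
})

test_that("GLCM matches hand enumeration on canonical fixtures", {
  full2 <- matrix(TRUE, 2, 2)
  # constant 2x2, offset (0,1), symmetric: p(0,0) = 1, 4 pairs
  q <- quantize_masked(matrix(5, 2, 2), full2, g = 2)
  glcm <- compute_glcm(q, c(0, 1), g = 2)
  expect_equal(glcm$n_pairs, 4)
  expect_equal(glcm$p[1, 1], 1)
  expect_equal(haralick_contrast(glcm), 0)
  expect_equal(haralick_entropy(glcm), 0)

  # 2-level checkerboard: all mass off-diagonal, contrast 1, entropy 1 bit
  cb <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  glcm <- compute_glcm(cb, c(0, 1), g = 2)
  expect_equal(glcm$p[1, 2], 0.5)
  expect_equal(glcm$p[2, 1], 0.5)
  expect_equal(glcm$p[1, 1] + glcm$p[2, 2], 0)
  expect_equal(haralick_contrast(glcm), 1)
  expect_equal(haralick_entropy(glcm), 1)

  # uniform GLCM over 16 cells: entropy log2(16) = 4 bits
  uni <- structure(list(p = matrix(1 / 16, 4, 4), g = 4L,
                        offset = c(0L, 1L), symmetric = TRUE,
                        n_pairs = 16), class = "glcm")
  expect_equal(haralick_entropy(uni), 4)

  # degenerate: mask breaks every pair
  q <- matrix(NA_integer_, 3, 3); q[, 2] <- 1L
  glcm <- compute_glcm(q, c(0, 1), g = 2)
  expect_equal(glcm$n_pairs, 0)
  expect_true(is.na(haralick_contrast(glcm)))
  expect_true(is.na(haralick_entropy(glcm)))

  expect_error(compute_glcm(cb, c(0, 0), g = 2), "invalid-offset")
})

test_that("GLCMs are normalised, symmetric and bounded on random regions", {
  set.seed(31)
  g <- 8
  for (rep in 1:10) {
    img <- matrix(runif(400), 20, 20)
    mask <- matrix(runif(400) > 0.3, 20, 20)
    if (!any(mask)) next
    q <- quantize_masked(img, mask, g = g)
    for (off in list(c(0, 3), c(3, 0), c(3, 3), c(3, -3))) {
      glcm <- compute_glcm(q, off, g = g)
      if (glcm$n_pairs == 0) next
      expect_equal(sum(glcm$p), 1)
      expect_identical(glcm$p, t(glcm$p))
      expect_true(haralick_contrast(glcm) >= 0 &&
                    haralick_contrast(glcm) <= (g - 1)^2)
      expect_true(haralick_entropy(glcm) >= 0 &&
                    haralick_entropy(glcm) <= 2 * log2(g))
    }
  }
})

test_that("texture matches exhaustive pair enumeration on random masked regions", {
  set.seed(32)
  for (rep in 1:8) {
    img <- matrix(sample(0:255, 144, TRUE), 12, 12)
    mask <- matrix(runif(144) > 0.25, 12, 12)
    q <- quantize_masked(img, mask, g = 6)
    for (off in list(c(0, 1), c(2, 0), c(1, 1), c(2, -1))) {
      glcm <- compute_glcm(q, off, g = 6)
      oracle <- enum_texture_oracle(q, off)
      expect_equal(glcm$n_pairs, oracle$n_pairs)
      if (oracle$n_pairs > 0) {
        expect_equal(haralick_contrast(glcm), oracle$contrast,
                     tolerance = 1e-12)
        expect_equal(haralick_entropy(glcm), oracle$entropy,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("texture is invariant to affine intensity rescaling", {
  set.seed(33)
  img <- matrix(runif(900, 0, 4000), 30, 30)
  mask <- matrix(TRUE, 30, 30)
  a <- measure_texture(img, mask)
  b <- measure_texture(img * 3 + 7, mask)
  expect_equal(a$contrast, b$contrast, tolerance = 1e-12)
  expect_equal(a$entropy, b$entropy, tolerance = 1e-12)
})

test_that("per-cell measurement recovers constants and ground truth", {
  nucleus <- matrix(FALSE, 20, 20); nucleus[8:12, 8:12] <- TRUE
  cyto <- matrix(FALSE, 20, 20); cyto[4:16, 4:16] <- TRUE
  set.seed(34)
  chans <- list(dapi = matrix(0, 20, 20),
                phalloidin = matrix(runif(400, 0, 100), 20, 20),
                runx2 = matrix(42, 20, 20))
  row <- measure_cell(chans, nucleus, cyto)
  expect_equal(row$runx2_mean, 42)
  expect_equal(row$runx2_integrated, 42 * sum(nucleus))
  expect_equal(row$nucleus_area, sum(nucleus))
  expect_false(row$qc_texture_degenerate)
  # per-direction columns present and averaged
  expect_equal(row$contrast,
               mean(c(row$contrast_deg0, row$contrast_deg90,
                      row$contrast_deg45, row$contrast_deg135)))

  expect_error(measure_cell(chans, cyto, nucleus), "outside")

  # noiseless synthetic cells through ground-truth masks: exact recovery
  sc <- generate_scene(small_scene_spec(n_cells = 3L, noise = NULL,
                                        seed = 44L))
  ch <- split_channels(max_intensity_projection(sc$stack))
  cells <- measure_cells(ch, sc$truth$nucleus_mask, sc$truth$cytoplasm_mask)
  expect_equal(cells$runx2_mean,
               sc$truth$cells$runx2_true_mean[order(sc$truth$cells$cell_id)])
})

test_that("degenerate cytoplasm regions are flagged, not crashed", {
  nucleus <- matrix(FALSE, 10, 10); nucleus[5, 5] <- TRUE
  cyto <- nucleus  # single pixel: no pair at distance 3 in any direction
  chans <- list(phalloidin = matrix(1, 10, 10), runx2 = matrix(1, 10, 10))
  row <- measure_cell(chans, nucleus, cyto, texture_params(d = 3))
  expect_true(row$qc_texture_degenerate)
  expect_true(is.na(row$contrast))
})
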