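# A noiseless DAPI image of ideal disks at given centres/radii.
disk_image <- function(size, centres, radius, value = 1000) {
  img <- matrix(0, size, size)
  for (i in seq_len(nrow(centres))) {
    rr <- outer((seq_len(size) - centres[i, 1])^2, rep(1, size), "+")
    cc <- outer(rep(1, size), (seq_len(size) - centres[i, 2])^2)
    img[rr + cc <= radius^2] <- value
  }
  img
}

test_that("well-separated nuclei are found with accurate centroids", {
  sc <- generate_scene(small_scene_spec(n_cells = 5L, noise = NULL,
                                        seed = 17L))
  ch <- split_channels(max_intensity_projection(sc$stack))
  seg <- segment_nuclei(ch$dapi)
  expect_equal(max(seg$mask), 5)
  truth <- sc$truth$cells[order(sc$truth$cells$centroid_row,
                                sc$truth$cells$centroid_col), ]
  for (k in seq_len(5)) {
    idx <- which(seg$mask == k, arr.ind = TRUE)
    cent <- colMeans(idx)
    expect_lt(sqrt((cent[1] - truth$centroid_row[k])^2 +
                     (cent[2] - truth$centroid_col[k])^2), 2)
  }
})

test_that("blank images yield zero nuclei with a warning, not an error", {
  expect_warning(seg <- segment_nuclei(matrix(0, 64, 64)), "blank|constant")
  expect_equal(max(seg$mask), 0)
  expect_equal(nrow(seg$report), 0)
})

test_that("fused nuclei are declumped by watershed or reported oversized", {
  img <- disk_image(96, rbind(c(48, 38), c(48, 58)), radius = 12)
  seg <- segment_nuclei(img, seg_params(sigma = 1, min_area = 100,
                                        max_area = 500))
  filt <- filter_isolated_cells(seg$mask, seg_params(min_area = 100,
                                                     max_area = 500,
                                                     r_touch = 0))
  declumped <- max(seg$mask) == 2
  oversized <- any(filt$report$reason == "too_large")
  expect_true(declumped || oversized)
  if (declumped) {
    cents <- t(sapply(1:2, function(k)
      colMeans(which(seg$mask == k, arr.ind = TRUE))))
    expect_lt(abs(cents[1, 1] - 48), 3)
    expect_lt(abs(cents[2, 1] - 48), 3)
  }
})

test_that("segmentation is deterministic", {
  sc <- generate_scene(small_scene_spec(n_cells = 6L, seed = 2L))
  ch <- split_channels(max_intensity_projection(sc$stack))
  s1 <- segment_nuclei(ch$dapi)
  s2 <- segment_nuclei(ch$dapi)
  expect_identical(s1$mask, s2$mask)
  c1 <- propagate_cytoplasm(s1$mask, ch$phalloidin)
  c2 <- propagate_cytoplasm(s2$mask, ch$phalloidin)
  expect_identical(c1, c2)
})

test_that("border, size and touching exclusions fire with recorded reasons", {
  # object with a pixel on the image edge
  mask <- matrix(0L, 32, 32)
  mask[1:6, 10:15] <- 1L
  mask[20:27, 10:17] <- 2L
  filt <- filter_isolated_cells(mask, seg_params(min_area = 30,
                                                 max_area = 200,
                                                 min_solidity = 0.5))
  expect_equal(filt$report$reason[filt$report$label == 1], "border")
  expect_true(filt$report$kept[filt$report$label == 2])
  expect_equal(max(filt$mask), 1)

  # two nuclei 1 px apart with r_touch = 3: both excluded
  mask <- matrix(0L, 40, 40)
  mask[10:18, 5:14] <- 1L
  mask[10:18, 16:25] <- 2L
  filt <- filter_isolated_cells(mask, seg_params(min_area = 30,
                                                 max_area = 200,
                                                 min_solidity = 0.5,
                                                 r_touch = 3))
  expect_equal(filt$report$reason, c("touching", "touching"))
  expect_equal(max(filt$mask), 0)
  # with r_touch = 1 the 1-px gap is tolerated
  filt2 <- filter_isolated_cells(mask, seg_params(min_area = 30,
                                                  max_area = 200,
                                                  min_solidity = 0.5,
                                                  r_touch = 1))
  expect_true(all(filt2$report$kept))

  # area rules
  mask <- matrix(0L, 40, 40)
  mask[5:6, 5:6] <- 1L          # 4 px, too small
  mask[15:34, 5:34] <- 2L       # 600 px, too large
  filt <- filter_isolated_cells(mask, seg_params(min_area = 30,
                                                 max_area = 200,
                                                 min_solidity = 0.5))
  expect_equal(sort(filt$report$reason), c("too_large", "too_small"))
})

test_that("interior well-separated scenes pass QC with zero exclusions", {
  sc <- generate_scene(small_scene_spec(n_cells = 5L, seed = 23L))
  ch <- split_channels(max_intensity_projection(sc$stack))
  seg <- segment_nuclei(ch$dapi)
  filt <- filter_isolated_cells(seg$mask)
  expect_true(all(filt$report$kept))
  expect_equal(max(filt$mask), 5)
})

test_that("cytoplasm propagation respects ownership and containment", {
  sc <- generate_scene(small_scene_spec(n_cells = 3L, seed = 9L))
  ch <- split_channels(max_intensity_projection(sc$stack))
  seg <- segment_nuclei(ch$dapi)
  filt <- filter_isolated_cells(seg$mask)
  cyto <- propagate_cytoplasm(filt$mask, ch$phalloidin)
  expect_silent(check_containment(filt$mask, cyto))
  # labels contiguous
  expect_setequal(setdiff(unique(as.vector(cyto)), 0),
                  seq_len(max(filt$mask)))

  # Jaccard overlap with ground truth per cell (matched by centroid order)
  truth <- sc$truth$cells[order(sc$truth$cells$centroid_row,
                                sc$truth$cells$centroid_col), ]
  for (k in seq_len(max(filt$mask))) {
    est <- cyto == k
    gt <- sc$truth$cytoplasm_mask == truth$cell_id[k]
    jacc <- sum(est & gt) / sum(est | gt)
    expect_gt(jacc, 0.8)
    # no pixel of another cell's ground-truth region claimed
    other <- sc$truth$cytoplasm_mask != 0 &
      sc$truth$cytoplasm_mask != truth$cell_id[k]
    expect_equal(sum(est & other), 0)
  }

  expect_equal(max(propagate_cytoplasm(matrix(0L, 32, 32),
                                       matrix(0, 32, 32))), 0)
})
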