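#' Maximum-intensity projection of a multichannel z-stack
#'
#' Collapses each channel of an `image_stack` to 2-D by the per-pixel
#' maximum over planes, the standard projection for sparse fluorescent
#' structures. Idempotent on a single-plane stack.
#'
#' @param stack An `image_stack` (list of 3-D `[row, col, plane]` arrays for
#'   channels `dapi`, `phalloidin`, `runx2`), as returned in
#'   [generate_scene()]`$stack` or by [read_stack()].
#' @return An object of class `projection_image`: list with `channels`
#'   (named list of 2-D matrices), `method = "max"`, `pixel_size`,
#'   `bit_depth`.
#' @export
max_intensity_projection <- function(stack) {
  chans <- c("dapi", "phalloidin", "runx2")
  present <- chans[chans %in% names(stack)]
  if (length(present) == 0) stop("no image channels found", call. = FALSE)
  dims <- lapply(stack[present], dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("structural error: channels have mismatched dimensions", call. = FALSE)
  }
  if (length(dims[[1]]) != 3 || dims[[1]][3] < 1) {
    stop("structural error: each channel must be a [row, col, plane] array ",
         "with >= 1 plane", call. = FALSE)
  }
  proj <- lapply(stack[present], function(arr) {
    Reduce(pmax, lapply(seq_len(dim(arr)[3]), function(p) arr[, , p]))
  })
  structure(list(channels = proj, method = "max",
                 pixel_size = stack$pixel_size,
                 bit_depth = stack$bit_depth),
            class = "projection_image")
}

#' Split a projection into its greyscale channels
#'
#' Returns the three stain channels by name, in stable order
#' (dapi, phalloidin, runx2).
#'
#' @param proj A `projection_image`.
#' @return Named list of three 2-D matrices.
#' @export
split_channels <- function(proj) {
  stopifnot(inherits(proj, "projection_image"))
  need <- c("dapi", "phalloidin", "runx2")
  missing <- setdiff(need, names(proj$channels))
  if (length(missing)) {
    stop("missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  proj$channels[need]
}

#' Segmentation parameters
#'
#' Settings for nucleus segmentation and isolated-cell quality control.
#' The reference analysis removed overlapping and bordered cells by hand;
#' here the exclusion is automated with four explicit rules (border, area
#' range, solidity, proximity) so the pipeline is reproducible.
#'
#' @param sigma Gaussian smoothing sigma (pixels) before thresholding.
#' @param threshold `"otsu"` for a global Otsu threshold, or a fixed numeric
#'   threshold on raw intensity.
#' @param watershed_tolerance Minimum depth (in distance-map units) for
#'   watershed declumping of touching nuclei.
#' @param min_area,max_area Nucleus area bounds in pixels.
#' @param min_solidity Minimum solidity (area / convex area).
#' @param r_touch Exclusion radius in pixels: objects whose masks lie within
#'   this distance of another object are dropped as touching.
#' @param lambda Regularisation of the intensity-weighted propagation used
#'   for cytoplasm identification (0 = pure intensity, large = pure
#'   distance).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(sigma = 2, threshold = "otsu",
                       watershed_tolerance = 2,
                       min_area = 80, max_area = 2500,
                       min_solidity = 0.85, r_touch = 3,
                       lambda = 1e-4) {
  structure(list(sigma = sigma, threshold = threshold,
                 watershed_tolerance = watershed_tolerance,
                 min_area = min_area, max_area = max_area,
                 min_solidity = min_solidity, r_touch = r_touch,
                 lambda = lambda),
            class = "seg_params")
}

# Renumber a label mask 1..K ordered by object centroid (row, then col).
relabel_by_centroid <- function(mask) {
  labs <- setdiff(sort(unique(as.vector(mask))), 0)
  if (length(labs) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  cent <- t(vapply(labs, function(l) {
    idx <- which(mask == l, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }, numeric(2)))
  ord <- order(cent[, 1], cent[, 2])
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_along(ord)) out[mask == labs[ord[i]]] <- i
  out
}

label_centroids <- function(mask) {
  labs <- setdiff(sort(unique(as.vector(mask))), 0)
  t(vapply(labs, function(l) {
    idx <- which(mask == l, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }, numeric(2)))
}

#' Segment nuclei from a DAPI image
#'
#' Gaussian smoothing, global Otsu threshold, connected components and
#' distance-transform watershed declumping of touching nuclei; obvious
#' specks below half the minimum area are dropped here, all other
#' exclusions are left to [filter_isolated_cells()] so they are reported.
#' Labels are ordered by centroid (row, then column) and segmentation is
#' deterministic.
#'
#' @param dapi 2-D numeric matrix.
#' @param params A [seg_params()].
#' @return List with `mask` (integer label matrix) and `report` (data frame
#'   of candidate objects: label, area, centroid).
#' @export
segment_nuclei <- function(dapi, params = seg_params()) {
  stopifnot(is.matrix(dapi))
  rng <- range(dapi)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    warning("blank or constant DAPI image: no nuclei found", call. = FALSE)
    return(list(mask = matrix(0L, nrow(dapi), ncol(dapi)),
                report = data.frame(label = integer(0), area = integer(0),
                                    centroid_row = numeric(0),
                                    centroid_col = numeric(0))))
  }
  img <- (dapi - rng[1]) / diff(rng)
  smoothed <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                       sigma = params$sigma))
  thr <- if (identical(params$threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(smoothed), range = c(0, 1), levels = 256)
  } else {
    (params$threshold - rng[1]) / diff(rng)
  }
  bw <- smoothed > thr
  if (!any(bw)) {
    warning("no foreground above threshold: no nuclei found", call. = FALSE)
    return(list(mask = matrix(0L, nrow(dapi), ncol(dapi)),
                report = data.frame(label = integer(0), area = integer(0),
                                    centroid_row = numeric(0),
                                    centroid_col = numeric(0))))
  }
  dm <- EBImage::distmap(bw)
  labels <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                               ext = 1)
  labels <- as.matrix(labels)
  # drop specks too small to be a nucleus fragment
  tab <- tabulate(labels[labels > 0])
  specks <- which(tab < params$min_area / 2)
  if (length(specks)) labels[labels %in% specks] <- 0L
  mask <- relabel_by_centroid(labels)
  labs <- setdiff(sort(unique(as.vector(mask))), 0)
  cent <- if (length(labs)) label_centroids(mask) else
    matrix(numeric(0), ncol = 2)
  report <- data.frame(label = labs,
                       area = tabulate(mask[mask > 0], nbins = length(labs)),
                       centroid_row = cent[, 1], centroid_col = cent[, 2])
  list(mask = mask, report = report)
}

# Solidity = pixel area / convex hull area (hull polygon area corrected for
# pixel extent by Pick's-theorem-style boundary term).
object_solidity <- function(idx) {
  if (nrow(idx) < 4) return(1)
  pts <- unique(idx)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[hull, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(1)
  x <- hp[, 2]; y <- hp[, 1]
  poly_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  hull_area <- poly_area + n / 2 + 1
  min(1, nrow(idx) / hull_area)
}

# Boundary pixels of one object (pixels with a 4-neighbour outside it).
object_boundary <- function(mask, label) {
  obj <- mask == label
  h <- nrow(obj); w <- ncol(obj)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- obj & shift(obj, 1, 0) & shift(obj, -1, 0) &
    shift(obj, 0, 1) & shift(obj, 0, -1)
  which(obj & !interior, arr.ind = TRUE)
}

#' Remove bordered, mis-sized, irregular and touching nuclei
#'
#' Automated counterpart of the manual curation step that kept only
#' isolated cells: excludes nuclei that (a) touch the image border,
#' (b) have area outside `[min_area, max_area]`, (c) have solidity below
#' `min_solidity`, or (d) lie within `r_touch` pixels of another nucleus
#' (both members of a touching pair are dropped). Remaining labels are
#' renumbered contiguously and every candidate's fate is reported.
#'
#' @param mask Integer nucleus label mask.
#' @param params A [seg_params()].
#' @return List with `mask` (filtered, renumbered label matrix) and
#'   `report` (data frame: label, kept, reason in
#'   `none|border|too_small|too_large|low_solidity|touching`, area,
#'   centroid).
#' @export
filter_isolated_cells <- function(mask, params = seg_params()) {
  stopifnot(is.matrix(mask))
  labs <- setdiff(sort(unique(as.vector(mask))), 0)
  n <- length(labs)
  if (n == 0) {
    return(list(mask = matrix(0L, nrow(mask), ncol(mask)),
                report = data.frame(label = integer(0), kept = logical(0),
                                    reason = character(0), area = integer(0),
                                    centroid_row = numeric(0),
                                    centroid_col = numeric(0))))
  }
  h <- nrow(mask); w <- ncol(mask)
  reason <- rep("none", n)
  area <- integer(n)
  cent <- matrix(0, n, 2)
  idx_list <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- which(mask == labs[i], arr.ind = TRUE)
    idx_list[[i]] <- idx
    area[i] <- nrow(idx)
    cent[i, ] <- c(mean(idx[, 1]), mean(idx[, 2]))
    if (any(idx[, 1] == 1 | idx[, 1] == h | idx[, 2] == 1 | idx[, 2] == w)) {
      reason[i] <- "border"
    } else if (area[i] < params$min_area) {
      reason[i] <- "too_small"
    } else if (area[i] > params$max_area) {
      reason[i] <- "too_large"
    } else if (object_solidity(idx) < params$min_solidity) {
      reason[i] <- "low_solidity"
    }
  }
  # touching: min boundary-to-boundary distance <= r_touch, checked only for
  # pairs whose bounding boxes expanded by r_touch intersect
  if (n > 1) {
    bbox <- t(vapply(idx_list, function(idx)
      c(range(idx[, 1]), range(idx[, 2])), numeric(4)))
    bnd <- lapply(seq_len(n), function(i) object_boundary(mask, labs[i]))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (bbox[i, 1] > bbox[j, 2] + params$r_touch ||
          bbox[j, 1] > bbox[i, 2] + params$r_touch ||
          bbox[i, 3] > bbox[j, 4] + params$r_touch ||
          bbox[j, 3] > bbox[i, 4] + params$r_touch) next
      bi <- bnd[[i]]; bj <- bnd[[j]]
      d2 <- outer(bi[, 1], bj[, 1], "-")^2 + outer(bi[, 2], bj[, 2], "-")^2
      if (min(d2) <= params$r_touch^2) {
        reason[i] <- "touching"
        reason[j] <- "touching"
      }
    }
  }
  kept <- reason == "none"
  out <- matrix(0L, h, w)
  new_id <- 0L
  keep_order <- order(cent[, 1], cent[, 2])
  for (i in keep_order) {
    if (!kept[i]) next
    new_id <- new_id + 1L
    out[mask == labs[i]] <- new_id
  }
  list(mask = out,
       report = data.frame(label = labs, kept = kept, reason = reason,
                           area = area, centroid_row = cent[, 1],
                           centroid_col = cent[, 2]))
}

#' Identify the cytoplasm belonging to each nucleus
#'
#' Finds actin-positive foreground by a global Otsu threshold on the
#' phalloidin image and assigns each foreground pixel to a nucleus by
#' intensity-weighted propagation from the nucleus seeds (the
#' CellProfiler-style secondary-object strategy): pixels are claimed along
#' paths minimising a geodesic cost mixing image-intensity differences and
#' spatial distance, controlled by `lambda`. Each cytoplasm label contains
#' its nucleus; foreground unreachable from any seed stays background.
#'
#' @param nuclei QC-filtered nucleus label mask.
#' @param phalloidin 2-D numeric actin image.
#' @param params A [seg_params()].
#' @return Integer cytoplasm label mask, labels matching `nuclei`.
#' @export
propagate_cytoplasm <- function(nuclei, phalloidin, params = seg_params()) {
  stopifnot(is.matrix(nuclei), is.matrix(phalloidin),
            all(dim(nuclei) == dim(phalloidin)))
  if (max(nuclei) == 0) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  rng <- range(phalloidin)
  img <- if (diff(rng) > 0) (phalloidin - rng[1]) / diff(rng) else
    matrix(0, nrow(phalloidin), ncol(phalloidin))
  # smooth before thresholding so the gaps between filaments stay inside the
  # cytoplasm foreground; the raw image still drives the propagation cost
  smoothed <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                       sigma = params$sigma))
  thr <- if (identical(params$threshold, "otsu") && diff(rng) > 0) {
    EBImage::otsu(EBImage::Image(smoothed), range = c(0, 1), levels = 256)
  } else if (is.numeric(params$threshold)) {
    (params$threshold - rng[1]) / max(diff(rng), 1)
  } else 0.5
  fg <- smoothed > thr | nuclei > 0
  cyto <- EBImage::propagate(EBImage::Image(img), seeds = nuclei, mask = fg,
                             lambda = params$lambda)
  cyto <- as.matrix(cyto)
  storage.mode(cyto) <- "integer"
  # containment guard: a nucleus whose surroundings fall below threshold
  # keeps at least its own region
  bare <- setdiff(unique(nuclei[nuclei > 0]), unique(cyto[cyto > 0]))
  if (length(bare)) {
    warning("nucleus with no surrounding actin foreground: cytoplasm set to ",
            "the nucleus region for label(s) ",
            paste(bare, collapse = ", "), call. = FALSE)
  }
  cyto[nuclei > 0] <- nuclei[nuclei > 0]
  cyto
}

#' Verify nucleus-in-cytoplasm containment
#'
#' Checks that every nucleus label's region is contained in the same label's
#' cytoplasm region, the structural invariant behind per-cell measurement.
#'
#' @param nuclei,cytoplasm Matching label masks.
#' @return `TRUE` invisibly; error otherwise.
#' @export
check_containment <- function(nuclei, cytoplasm) {
  bad <- nuclei > 0 & cytoplasm != nuclei
  if (any(bad)) {
    stop("containment violated: ", sum(bad),
         " nucleus pixel(s) outside their cytoplasm label", call. = FALSE)
  }
  invisible(TRUE)
}
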