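#' Actin phenotype specification
#'
#' Parameters of the two cytoskeletal phenotypes the simulator can render in
#' the phalloidin channel:
#' \describe{
#'   \item{`homogeneous_filaments`}{many thin, roughly aligned filaments
#'     spread across the whole cytoplasm — the undifferentiated hMSC actin
#'     network.}
#'   \item{`peripheral_stress_fibres`}{a few thick, bright actin bundles
#'     confined to the outer rim of the cell with a dimmer interior — the
#'     osteogenic phenotype.}
#' }
#' Both phenotypes are rendered at a matched whole-cell mean intensity, so
#' downstream texture differences reflect spatial organisation, not
#' brightness.
#'
#' @param kind `"homogeneous_filaments"` or `"peripheral_stress_fibres"`.
#' @param filament_count Number of filaments (thin kind) or stress-fibre
#'   arcs (peripheral kind); >= 1.
#' @param filament_thickness Filament thickness in pixels (>= 1).
#' @param filament_intensity Relative fluorescence amplitude of one filament
#'   against the diffuse cytoplasmic background (arbitrary units).
#' @param orientation_dispersion Standard deviation of filament orientation
#'   around the cell's principal direction, in degrees (thin kind).
#' @param peripheral_band_fraction Fraction of the cell radius occupied by
#'   the peripheral band holding the stress fibres (peripheral kind only);
#'   in (0, 1].
#' @return An object of class `phenotype_spec`.
#' @export
#' @examples
#' phenotype_spec("peripheral_stress_fibres")
phenotype_spec <- function(kind = c("homogeneous_filaments",
                                    "peripheral_stress_fibres"),
                           filament_count = NULL,
                           filament_thickness = NULL,
                           filament_intensity = NULL,
                           orientation_dispersion = 15,
                           peripheral_band_fraction = 0.25) {
  kind <- match.arg(kind)
  # Defaults are not taken from any published measurement: they encode the
  # qualitative descriptions (many thin dim filaments across the cell vs a
  # few thick bright peripheral bundles) at magnitudes consistent with a
  # 10x objective (~1.1 um pixels): thin bundles near the resolution limit
  # (~2 px), stress fibres several micrometres wide and markedly brighter.
  if (is.null(filament_count)) {
    filament_count <- if (kind == "homogeneous_filaments") 80L else 7L
  }
  if (is.null(filament_thickness)) {
    filament_thickness <- if (kind == "homogeneous_filaments") 2 else 5
  }
  if (is.null(filament_intensity)) {
    filament_intensity <- if (kind == "homogeneous_filaments") 0.4 else 10
  }
  if (filament_count < 1) stop("`filament_count` must be >= 1", call. = FALSE)
  if (filament_thickness < 1) {
    stop("`filament_thickness` must be >= 1 pixel", call. = FALSE)
  }
  if (filament_intensity <= 0) {
    stop("`filament_intensity` must be > 0", call. = FALSE)
  }
  if (orientation_dispersion < 0) {
    stop("`orientation_dispersion` must be >= 0", call. = FALSE)
  }
  if (peripheral_band_fraction <= 0 || peripheral_band_fraction > 1) {
    stop("`peripheral_band_fraction` must be in (0, 1]", call. = FALSE)
  }
  structure(list(kind = kind,
                 filament_count = as.integer(filament_count),
                 filament_thickness = filament_thickness,
                 filament_intensity = filament_intensity,
                 orientation_dispersion = orientation_dispersion,
                 peripheral_band_fraction = peripheral_band_fraction),
            class = "phenotype_spec")
}

#' Synthetic scene specification
#'
#' Full description of one simulated confocal field of view. Defaults follow
#' the acquisition geometry of the reference experiment: 1024 x 1024 pixels,
#' 20 z-planes at 5 micrometre spacing, 10x objective (pixel size
#' 1.14 micrometre). Intensities are in arbitrary fluorescence units on a
#' 16-bit scale.
#'
#' @param image_size Integer vector `c(rows, cols)`.
#' @param n_planes Number of z-planes (>= 1).
#' @param pixel_size Lateral pixel size in micrometres.
#' @param n_cells Number of cells to place (>= 0).
#' @param cell_radius_range Range `c(min, max)` of the major semi-axis of the
#'   cell (cytoplasm) ellipse, in pixels.
#' @param nucleus_radius_range Range of the nucleus major semi-axis, pixels.
#' @param runx2_mean,runx2_sd Mean and standard deviation of the per-cell
#'   nuclear marker intensity for this experimental group.
#' @param dapi_mean Nuclear DAPI intensity.
#' @param actin_mean Target whole-cell mean phalloidin intensity (identical
#'   for both phenotypes; enforced by renormalisation).
#' @param phenotype A [phenotype_spec()].
#' @param noise `NULL` for a noiseless scene, or a list with elements
#'   `poisson_scale` (photons per intensity unit; larger = less shot noise),
#'   `gaussian_sd` (additive read noise, intensity units) and
#'   `background_level` (constant offset, intensity units).
#' @param min_cell_separation Minimum centre-to-centre distance between
#'   cells in pixels; `NULL` computes a non-overlapping default from the
#'   cell radius range.
#' @param allow_border_cells Allow cells clipped by the image border.
#' @param allow_overlaps Allow overlapping cells (ground-truth masks then
#'   resolve overlaps by cell order).
#' @param axial_sigma Axial extent of a cell's signal, in planes, for the
#'   Gaussian z-profile.
#' @param bit_depth Output bit depth (pixel values clipped to
#'   `[0, 2^bit_depth - 1]` and rounded).
#' @param seed Integer seed; the scene is a pure function of (spec, seed).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(1024L, 1024L),
                       n_planes = 20L,
                       pixel_size = 1.14,
                       n_cells = 10L,
                       cell_radius_range = c(28, 42),
                       nucleus_radius_range = c(10, 15),
                       runx2_mean = 2000,
                       runx2_sd = 250,
                       dapi_mean = 9000,
                       actin_mean = 3000,
                       phenotype = phenotype_spec("homogeneous_filaments"),
                       noise = list(poisson_scale = 0.5, gaussian_sd = 20,
                                    background_level = 100),
                       min_cell_separation = NULL,
                       allow_border_cells = FALSE,
                       allow_overlaps = FALSE,
                       axial_sigma = 1.5,
                       bit_depth = 16L,
                       seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 16),
            n_planes >= 1, n_cells >= 0,
            length(cell_radius_range) == 2,
            all(cell_radius_range > 0), diff(cell_radius_range) >= 0,
            length(nucleus_radius_range) == 2,
            all(nucleus_radius_range > 0), diff(nucleus_radius_range) >= 0,
            nucleus_radius_range[2] < cell_radius_range[1],
            runx2_mean > 0, runx2_sd >= 0, dapi_mean > 0, actin_mean > 0,
            inherits(phenotype, "phenotype_spec"),
            axial_sigma > 0, bit_depth >= 8)
  if (!is.null(noise)) {
    stopifnot(is.list(noise), noise$poisson_scale > 0, noise$gaussian_sd >= 0,
              noise$background_level >= 0)
  }
  if (is.null(min_cell_separation)) {
    min_cell_separation <- 2 * cell_radius_range[2] + 5
  }
  structure(list(image_size = as.integer(image_size),
                 n_planes = as.integer(n_planes), pixel_size = pixel_size,
                 n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range,
                 nucleus_radius_range = nucleus_radius_range,
                 runx2_mean = runx2_mean, runx2_sd = runx2_sd,
                 dapi_mean = dapi_mean, actin_mean = actin_mean,
                 phenotype = phenotype, noise = noise,
                 min_cell_separation = min_cell_separation,
                 allow_border_cells = isTRUE(allow_border_cells),
                 allow_overlaps = isTRUE(allow_overlaps),
                 axial_sigma = axial_sigma,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Elliptical coordinates of a pixel grid around a cell centre.
# Returns the normalised radial fraction rho (1 on the ellipse boundary)
# and the angle phi in the ellipse frame, for the given window rows/cols.
ellipse_coords <- function(rows, cols, centre, semi_axes, theta) {
  dr <- outer(rows - centre[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - centre[2])
  # rotate into the ellipse frame (row = y down, col = x right)
  u <- cos(theta) * dc + sin(theta) * dr
  v <- -sin(theta) * dc + cos(theta) * dr
  rho <- sqrt((u / semi_axes[1])^2 + (v / semi_axes[2])^2)
  list(rho = rho, phi = atan2(v, u), u = u, v = v)
}

#' Render the actin layer of a single cell
#'
#' Draws the phalloidin (actin) signal of one cell into a local window,
#' according to its phenotype, and rescales it so the mean intensity over
#' the cytoplasm mask is exactly 1 (the caller multiplies by the scene's
#' `actin_mean`). Thin filaments are drawn as anti-aliased chords with a
#' Gaussian cross profile over a faint diffuse cortical background; stress
#' fibres as thick bright arcs confined to the peripheral annulus over a
#' dimmer interior.
#'
#' Consumes the R random number stream, so results are reproducible under an
#' enclosing `set.seed()`.
#'
#' @param cell A list with elements `centre` (row, col), `semi_axes`
#'   (major, minor, pixels) and `theta` (orientation, radians).
#' @param phenotype A [phenotype_spec()].
#' @param rows,cols Integer vectors of the window rows and columns
#'   (absolute image coordinates) into which the cell is rendered.
#' @return A `length(rows) x length(cols)` numeric matrix, zero outside the
#'   cell, with mean exactly 1 over the cytoplasm pixels.
#' @export
render_phenotype <- function(cell, phenotype, rows, cols) {
  stopifnot(inherits(phenotype, "phenotype_spec"))
  ec <- ellipse_coords(rows, cols, cell$centre, cell$semi_axes, cell$theta)
  inside <- ec$rho <= 1
  layer <- matrix(0, length(rows), length(cols))
  if (!any(inside)) return(layer)
  thick_sigma <- phenotype$filament_thickness / 2.355  # FWHM -> sigma
  if (phenotype$kind == "homogeneous_filaments") {
    # faint diffuse cortical mesh under the filaments
    layer[inside] <- 0.3
    disp <- phenotype$orientation_dispersion * pi / 180
    theta0 <- stats::runif(1, 0, pi)
    r_major <- cell$semi_axes[1]
    for (i in seq_len(phenotype$filament_count)) {
      ang <- theta0 + stats::rnorm(1, 0, disp)
      offset <- stats::runif(1, -0.9, 0.9) * r_major
      # distance from the infinite line at `offset` along the normal of `ang`,
      # in the cell frame (u, v); the cytoplasm mask clips it to a chord
      dist <- abs(-sin(ang) * ec$u + cos(ang) * ec$v - offset)
      layer <- layer + phenotype$filament_intensity *
        exp(-dist^2 / (2 * thick_sigma^2)) * inside
    }
  } else {
    band <- phenotype$peripheral_band_fraction
    # dim interior with a mild radial gradient (cortical actin remnant)
    layer[inside] <- 0.25 * (0.6 + 0.4 * ec$rho[inside])
    r_major <- cell$semi_axes[1]
    for (i in seq_len(phenotype$filament_count)) {
      rho0 <- stats::runif(1, 1 - band * 0.8, 1 - band * 0.1)
      phi0 <- stats::runif(1, -pi, pi)
      half_ang <- stats::runif(1, pi / 6, pi / 2.5)
      # individual fibre bundles vary in brightness and calibre
      inten <- phenotype$filament_intensity * stats::runif(1, 0.5, 1.5)
      band_sigma <- phenotype$filament_thickness * stats::runif(1, 0.8, 1.3) /
        2.355 / r_major
      dphi <- abs(((ec$phi - phi0 + pi) %% (2 * pi)) - pi)
      radial <- exp(-(ec$rho - rho0)^2 / (2 * band_sigma^2))
      angular <- dphi <= half_ang
      layer <- layer + inten * radial * angular * inside
    }
  }
  m <- mean(layer[inside])
  if (m > 0) layer[inside] <- layer[inside] / m
  layer
}

place_cells <- function(spec, max_retries = 1000L) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cells <- vector("list", spec$n_cells)
  centres <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(spec$n_cells)) {
    r_major <- stats::runif(1, spec$cell_radius_range[1],
                            spec$cell_radius_range[2])
    axis_ratio <- stats::runif(1, 0.7, 1)
    theta <- stats::runif(1, 0, pi)
    margin <- if (spec$allow_border_cells) 1 else ceiling(r_major) + 2
    if (2 * margin >= min(h, w)) {
      stop("placement error: cell radius too large for the image at ",
           "`allow_border_cells = FALSE`", call. = FALSE)
    }
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      centre <- c(stats::runif(1, margin + 1, h - margin),
                  stats::runif(1, margin + 1, w - margin))
      ok <- TRUE
      if (!spec$allow_overlaps && nrow(centres) > 0) {
        d <- sqrt(rowSums(sweep(centres, 2, centre)^2))
        prev_r <- vapply(cells[seq_len(k - 1)],
                         function(c) c$semi_axes[1], numeric(1))
        ok <- all(d >= pmax(spec$min_cell_separation,
                            prev_r + r_major + 2))
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) {
      stop(sprintf(paste0("placement error: could not fit cell %d of %d at ",
                          "min_cell_separation = %.1f px after %d retries"),
                   k, spec$n_cells, spec$min_cell_separation, max_retries),
           call. = FALSE)
    }
    n_major <- stats::runif(1, spec$nucleus_radius_range[1],
                            spec$nucleus_radius_range[2])
    cells[[k]] <- list(centre = centre,
                       semi_axes = c(r_major, r_major * axis_ratio),
                       nucleus_axes = c(n_major, n_major * axis_ratio),
                       theta = theta)
    centres <- rbind(centres, centre)
  }
  cells
}

window_indices <- function(centre, radius, h, w) {
  rows <- max(1L, floor(centre[1] - radius)):min(h, ceiling(centre[1] + radius))
  cols <- max(1L, floor(centre[2] - radius)):min(w, ceiling(centre[2] + radius))
  list(rows = rows, cols = cols)
}

#' Generate a synthetic multichannel confocal scene
#'
#' Builds a 3-channel z-stack (DAPI: nuclei; phalloidin: actin cytoskeleton
#' rendered per phenotype; nuclear marker: nucleus regions at a per-cell
#' intensity drawn from the group distribution) together with exact ground
#' truth. Cells are placed by rejection sampling under the separation and
#' border constraints; each cell's signal is spread over z with a Gaussian
#' axial profile peaking at 1 on its centre plane, so a maximum-intensity
#' projection recovers the in-focus image. Optional noise applies, per
#' plane: scaled Poisson shot noise on signal plus background, additive
#' Gaussian read noise, then clipping and rounding at the stored bit depth.
#'
#' The scene is a deterministic function of the spec (including its seed):
#' the same call yields bit-identical stacks.
#'
#' @param spec A [scene_spec()].
#' @param max_retries Placement retries per cell before failing.
#' @return A list of class `scene` with elements:
#'   \item{stack}{`image_stack`: list of 3-D arrays `[row, col, plane]` per
#'     channel (`dapi`, `phalloidin`, `runx2`), plus `pixel_size`,
#'     `bit_depth`.}
#'   \item{truth}{`ground_truth`: `cells` data frame (id, centroid, radii,
#'     phenotype, rendered nuclear marker mean, centre plane), plus
#'     `nucleus_mask` and `cytoplasm_mask` label matrices and the echoed
#'     spec.}
#' @export
#' @examples
#' sc <- generate_scene(scene_spec(image_size = c(128, 128), n_planes = 3,
#'                                 n_cells = 2, noise = NULL, seed = 7))
#' sc$truth$cells
generate_scene <- function(spec, max_retries = 1000L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]; np <- spec$n_planes
  cells <- place_cells(spec, max_retries)

  dapi2d <- matrix(0, h, w)
  actin2d <- matrix(0, h, w)
  runx2d <- matrix(0, h, w)
  nucleus_mask <- matrix(0L, h, w)
  cyto_mask <- matrix(0L, h, w)
  max_val <- 2^spec$bit_depth - 1

  info <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    cell <- cells[[k]]
    win <- window_indices(cell$centre, cell$semi_axes[1] + 2, h, w)
    ec <- ellipse_coords(win$rows, win$cols, cell$centre, cell$semi_axes,
                         cell$theta)
    ecn <- ellipse_coords(win$rows, win$cols, cell$centre, cell$nucleus_axes,
                          cell$theta)
    cyto_in <- ec$rho <= 1
    nuc_in <- ecn$rho <= 1
    # nuclear marker intensity drawn per group, rounded to the stored grid so
    # ground truth states the rendered value
    rx_raw <- max(0, stats::rnorm(1, spec$runx2_mean, spec$runx2_sd))
    rx <- round(min(rx_raw, max_val))
    actin_layer <- render_phenotype(cell, spec$phenotype, win$rows, win$cols) *
      spec$actin_mean
    centre_plane <- if (np == 1) 1L else
      sample(seq(max(1L, np %/% 2 - 2L), min(np, np %/% 2 + 3L)), 1)

    sub_n <- nucleus_mask[win$rows, win$cols]
    sub_c <- cyto_mask[win$rows, win$cols]
    free_c <- cyto_in & sub_c == 0L
    free_n <- nuc_in & sub_n == 0L
    sub_c[free_c] <- k
    sub_n[free_n] <- k
    nucleus_mask[win$rows, win$cols] <- sub_n
    cyto_mask[win$rows, win$cols] <- sub_c

    dsub <- dapi2d[win$rows, win$cols]
    dsub[free_n] <- spec$dapi_mean
    dapi2d[win$rows, win$cols] <- dsub
    rsub <- runx2d[win$rows, win$cols]
    rsub[free_n] <- rx
    runx2d[win$rows, win$cols] <- rsub
    asub <- actin2d[win$rows, win$cols]
    asub[free_c] <- actin_layer[free_c]
    actin2d[win$rows, win$cols] <- asub

    info[[k]] <- data.frame(cell_id = k,
                            centroid_row = cell$centre[1],
                            centroid_col = cell$centre[2],
                            cell_radius = cell$semi_axes[1],
                            nucleus_radius = cell$nucleus_axes[1],
                            phenotype = spec$phenotype$kind,
                            runx2_true_mean = rx,
                            centre_plane = centre_plane)
  }
  truth_cells <- if (length(info)) do.call(rbind, info) else
    data.frame(cell_id = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), cell_radius = numeric(0),
               nucleus_radius = numeric(0), phenotype = character(0),
               runx2_true_mean = numeric(0), centre_plane = integer(0))

  # z-profiles: per-cell Gaussian weight across planes, peaking at 1
  build_stack <- function(img2d) {
    arr <- array(0, dim = c(h, w, np))
    if (nrow(truth_cells) == 0) return(arr)
    for (p in seq_len(np)) {
      plane <- matrix(0, h, w)
      for (k in seq_len(nrow(truth_cells))) {
        wgt <- exp(-(p - truth_cells$centre_plane[k])^2 /
                     (2 * spec$axial_sigma^2))
        if (wgt < 1e-3) next
        cw <- window_indices(c(truth_cells$centroid_row[k],
                               truth_cells$centroid_col[k]),
                             truth_cells$cell_radius[k] + 2, h, w)
        sel <- cyto_mask[cw$rows, cw$cols] == k
        sub <- plane[cw$rows, cw$cols]
        src <- img2d[cw$rows, cw$cols]
        sub[sel] <- src[sel] * wgt
        plane[cw$rows, cw$cols] <- sub
      }
      arr[, , p] <- plane
    }
    arr
  }

  stack <- list(dapi = build_stack(dapi2d),
                phalloidin = build_stack(actin2d),
                runx2 = build_stack(runx2d))

  if (!is.null(spec$noise)) {
    ps <- spec$noise$poisson_scale
    gsd <- spec$noise$gaussian_sd
    bg <- spec$noise$background_level
    for (ch in names(stack)) {
      lambda <- (stack[[ch]] + bg) * ps
      shot <- array(stats::rpois(length(lambda), lambda), dim = dim(lambda)) / ps
      read <- array(stats::rnorm(length(lambda), 0, gsd), dim = dim(lambda))
      stack[[ch]] <- shot + read
    }
  }
  for (ch in names(stack)) {
    stack[[ch]] <- round(pmin(pmax(stack[[ch]], 0), max_val))
  }

  stack <- structure(c(stack, list(pixel_size = spec$pixel_size,
                                   bit_depth = spec$bit_depth)),
                     class = "image_stack")
  truth <- structure(list(cells = truth_cells,
                          nucleus_mask = nucleus_mask,
                          cytoplasm_mask = cyto_mask,
                          seed = spec$seed, spec = spec),
                     class = "ground_truth")
  structure(list(stack = stack, truth = truth), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$stack$dapi)
  cat(sprintf("Synthetic confocal scene: %d x %d px, %d planes, %d cells (%s)\n",
              d[1], d[2], d[3], nrow(x$truth$cells),
              x$truth$spec$phenotype$kind))
  invisible(x)
}
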