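#' Quantize a masked image region to discrete grey levels
#'
#' Linearly rescales the intensities of the pixels inside `mask` from their
#' own `[min, max]` range into levels `0 .. g-1`:
#' `floor((v - min) / (max - min) * g)`, capped at `g - 1`. A constant
#' region maps entirely to level 0. Per-region min-max quantization makes
#' the downstream co-occurrence features invariant to affine rescaling of
#' the raw intensities (illumination changes).
#'
#' @param image 2-D numeric matrix.
#' @param mask Logical matrix of the same size (the region), or an integer
#'   label matrix together with `label`.
#' @param g Number of grey levels (>= 2).
#' @param label When `mask` is a label matrix, the label to quantize.
#' @return Integer matrix with levels in `0 .. g-1` inside the region and
#'   `NA` outside.
#' @export
#' @examples
#' m <- matrix(1:16, 4, 4)
#' quantize_masked(m, matrix(TRUE, 4, 4), g = 4)
quantize_masked <- function(image, mask, g = 8L, label = NULL) {
  stopifnot(is.matrix(image), g >= 2)
  g <- as.integer(g)
  if (!is.logical(mask)) {
    if (is.null(label)) stop("give `label` with an integer mask", call. = FALSE)
    mask <- mask == label
  }
  stopifnot(all(dim(mask) == dim(image)))
  if (!any(mask)) stop("empty-region error: mask selects no pixels",
                       call. = FALSE)
  v <- image[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi == lo) {
    q[mask] <- 0L
  } else {
    q[mask] <- pmin(as.integer(floor((v - lo) / (hi - lo) * g)), g - 1L)
  }
  q
}

#' Grey-level co-occurrence matrix of a masked region
#'
#' Counts ordered pairs of quantized levels `(q[p], q[p + offset])` over all
#' pixel positions `p` where both ends of the pair lie inside the region
#' (`NA` marks outside). With `symmetric = TRUE` the reversed offset is
#' added, making the matrix symmetric. The matrix is normalised to joint
#' probabilities by the pair count; a region admitting no pairs yields a
#' degenerate GLCM (`n_pairs = 0`), which the feature functions refuse.
#'
#' @param q Quantized integer matrix from [quantize_masked()] (`NA` outside
#'   the region).
#' @param offset Integer `c(drow, dcol)` displacement; not `c(0, 0)`.
#' @param g Number of grey levels.
#' @param symmetric Count each pair in both directions.
#' @return An object of class `glcm`: list with `p` (g x g probability
#'   matrix), `g`, `offset`, `symmetric`, `n_pairs`.
#' @export
#' @examples
#' q <- quantize_masked(matrix(c(0, 1, 0, 1), 2, 2), matrix(TRUE, 2, 2), g = 2)
#' compute_glcm(q, c(0, 1), g = 2)
compute_glcm <- function(q, offset, g, symmetric = TRUE) {
  stopifnot(is.matrix(q), length(offset) == 2)
  offset <- as.integer(offset)
  if (all(offset == 0L)) stop("invalid-offset error: offset must not be (0,0)",
                              call. = FALSE)
  h <- nrow(q); w <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  rows <- seq_len(h); cols <- seq_len(w)
  r_src <- rows[rows + dr >= 1 & rows + dr <= h]
  c_src <- cols[cols + dc >= 1 & cols + dc <= w]
  counts <- matrix(0, g, g)
  if (length(r_src) && length(c_src)) {
    a <- q[r_src, c_src, drop = FALSE]
    b <- q[r_src + dr, c_src + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      tab <- table(factor(a[ok], levels = 0:(g - 1)),
                   factor(b[ok], levels = 0:(g - 1)))
      counts <- counts + unclass(tab)
    }
  }
  if (symmetric) counts <- counts + t(counts)
  n_pairs <- as.integer(round(sum(counts)))
  p <- if (n_pairs > 0) counts / n_pairs else counts
  dimnames(p) <- NULL
  structure(list(p = p, g = as.integer(g), offset = offset,
                 symmetric = isTRUE(symmetric), n_pairs = n_pairs),
            class = "glcm")
}

#' Haralick contrast of a GLCM
#'
#' Sum of `(i - j)^2 p(i, j)` over the co-occurrence matrix: the local
#' intensity variation of the texture. Zero for a constant region; at most
#' `(g - 1)^2`.
#'
#' @param glcm A [compute_glcm()] result.
#' @return Contrast (dimensionless), or `NA` for a degenerate GLCM.
#' @export
haralick_contrast <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  if (glcm$n_pairs == 0) return(NA_real_)
  lv <- 0:(glcm$g - 1)
  d2 <- outer(lv, lv, "-")^2
  sum(d2 * glcm$p)
}

#' Haralick entropy of a GLCM
#'
#' Shannon entropy `-sum p(i, j) log2 p(i, j)` of the co-occurrence
#' distribution, in bits, with `0 log 0 = 0`: the complexity of the
#' texture. Zero for a constant region; at most `2 log2(g)`.
#'
#' @param glcm A [compute_glcm()] result.
#' @return Entropy in bits, or `NA` for a degenerate GLCM.
#' @export
haralick_entropy <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  if (glcm$n_pairs == 0) return(NA_real_)
  p <- glcm$p[glcm$p > 0]
  -sum(p * log2(p))
}

#' Texture parameters
#'
#' @param g Number of grey levels for quantization.
#' @param d Offset distance in pixels for co-occurrence pairs.
#' @param quantization `"region"` for per-object min-max quantization
#'   (default, illumination-robust) or `"image"` to quantize against the
#'   whole image's range.
#' @return A list of class `texture_params`.
#' @export
texture_params <- function(g = 8L, d = 3L, quantization = c("region", "image")) {
  stopifnot(g >= 2, d >= 1)
  structure(list(g = as.integer(g), d = as.integer(d),
                 quantization = match.arg(quantization)),
            class = "texture_params")
}

# The four standard Haralick directions at distance d:
# 0, 90, 45, 135 degrees in (drow, dcol) convention.
texture_offsets <- function(d) {
  list(deg0 = c(0L, d), deg90 = c(d, 0L), deg45 = c(d, d), deg135 = c(d, -d))
}

#' Masked Haralick texture of one region
#'
#' Quantizes the region and computes symmetric GLCMs in the four standard
#' directions (0, 45, 90, 135 degrees) at distance `d`, returning the
#' direction-averaged contrast and entropy plus the per-direction values.
#' Directions admitting no pixel pairs are dropped from the average; if no
#' direction admits pairs the texture is degenerate (`NA`, flagged).
#'
#' @param image 2-D numeric matrix (e.g. the phalloidin projection).
#' @param mask Logical region mask or integer label mask with `label`.
#' @param params A [texture_params()].
#' @param label Optional label when `mask` is an integer matrix.
#' @return A list of class `texture_measures`: `contrast`, `entropy`
#'   (direction averages, bits for entropy), `per_direction` (data frame),
#'   `n_pairs` (total), `degenerate` flag.
#' @export
measure_texture <- function(image, mask, params = texture_params(),
                            label = NULL) {
  q <- quantize_masked(image, mask, g = params$g, label = label)
  offs <- texture_offsets(params$d)
  per <- lapply(offs, function(off) {
    glcm <- compute_glcm(q, off, g = params$g, symmetric = TRUE)
    list(contrast = haralick_contrast(glcm),
         entropy = haralick_entropy(glcm),
         n_pairs = glcm$n_pairs)
  })
  pd <- data.frame(direction = names(offs),
                   contrast = vapply(per, `[[`, numeric(1), "contrast"),
                   entropy = vapply(per, `[[`, numeric(1), "entropy"),
                   n_pairs = vapply(per, `[[`, numeric(1), "n_pairs"),
                   row.names = NULL)
  valid <- pd$n_pairs > 0
  structure(list(
    contrast = if (any(valid)) mean(pd$contrast[valid]) else NA_real_,
    entropy = if (any(valid)) mean(pd$entropy[valid]) else NA_real_,
    per_direction = pd,
    n_pairs = sum(pd$n_pairs),
    degenerate = !any(valid)), class = "texture_measures")
}

#' Measure one cell
#'
#' Per-cell quantification: mean (and integrated) nuclear marker intensity
#' over the nucleus pixels from the marker channel, and masked Haralick
#' contrast and entropy of the actin channel over the cytoplasm pixels.
#'
#' @param channels Named list of 2-D matrices (`dapi`, `phalloidin`,
#'   `runx2`), as returned by [split_channels()].
#' @param nucleus_mask,cytoplasm_mask Logical masks of this cell's nucleus
#'   and cytoplasm (cytoplasm must contain the nucleus).
#' @param params A [texture_params()].
#' @param cell_id Identifier copied into the result.
#' @return One-row data frame: `cell_id`, `runx2_mean`, `runx2_integrated`,
#'   `contrast`, `entropy`, per-direction texture columns, `nucleus_area`,
#'   `cytoplasm_area`, `qc_texture_degenerate`.
#' @export
measure_cell <- function(channels, nucleus_mask, cytoplasm_mask,
                         params = texture_params(), cell_id = 1L) {
  stopifnot(any(nucleus_mask), any(cytoplasm_mask))
  if (any(nucleus_mask & !cytoplasm_mask)) {
    stop("nucleus mask extends outside the cytoplasm mask", call. = FALSE)
  }
  rx <- channels$runx2[nucleus_mask]
  tx <- measure_texture(channels$phalloidin, cytoplasm_mask, params)
  row <- data.frame(cell_id = cell_id,
                    runx2_mean = mean(rx),
                    runx2_integrated = sum(rx),
                    contrast = tx$contrast,
                    entropy = tx$entropy,
                    nucleus_area = sum(nucleus_mask),
                    cytoplasm_area = sum(cytoplasm_mask),
                    qc_texture_degenerate = tx$degenerate)
  for (i in seq_len(nrow(tx$per_direction))) {
    row[[paste0("contrast_", tx$per_direction$direction[i])]] <-
      tx$per_direction$contrast[i]
    row[[paste0("entropy_", tx$per_direction$direction[i])]] <-
      tx$per_direction$entropy[i]
  }
  row
}

#' Measure every cell of a segmented projection
#'
#' Applies [measure_cell()] to each label of the nucleus/cytoplasm mask
#' pair (labels must correspond).
#'
#' @param channels Named channel list from [split_channels()].
#' @param nuclei,cytoplasm Matching integer label masks.
#' @param params A [texture_params()].
#' @return Data frame with one row per cell.
#' @export
measure_cells <- function(channels, nuclei, cytoplasm,
                          params = texture_params()) {
  check_containment(nuclei, cytoplasm)
  labs <- setdiff(sort(unique(as.vector(nuclei))), 0)
  rows <- lapply(labs, function(l) {
    measure_cell(channels, nuclei == l, cytoplasm == l, params, cell_id = l)
  })
  if (length(rows) == 0) {
    return(measure_cell(list(runx2 = matrix(1, 2, 2),
                             phalloidin = matrix(1, 2, 2)),
                        matrix(TRUE, 2, 2), matrix(TRUE, 2, 2),
                        params)[0, ])
  }
  do.call(rbind, rows)
}
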