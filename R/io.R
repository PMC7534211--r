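#' Write an image stack as multipage TIFF files
#'
#' Writes one multipage 16-bit (or configured bit depth) TIFF per channel,
#' named `<prefix>_<channel>.tif`, with intensities scaled from
#' `[0, 2^bit_depth - 1]` to the TIFF unit range.
#'
#' @param stack An `image_stack`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  max_val <- 2^stack$bit_depth - 1
  paths <- character(0)
  for (ch in c("dapi", "phalloidin", "runx2")) {
    arr <- stack[[ch]]
    planes <- lapply(seq_len(dim(arr)[3]), function(p) arr[, , p] / max_val)
    path <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(planes, path, bits.per.sample = 16L)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read an image stack from multipage TIFF files
#'
#' Counterpart of [write_stack()]: reads the three channel files and
#' rescales to integer intensities at the stated bit depth.
#'
#' @param dir Directory holding the files.
#' @param prefix File name prefix used at write time.
#' @param pixel_size Lateral pixel size in micrometres (metadata).
#' @param bit_depth Intensity bit depth the files encode.
#' @return An `image_stack`.
#' @export
read_stack <- function(dir, prefix = "stack", pixel_size = 1.14,
                       bit_depth = 16L) {
  max_val <- 2^bit_depth - 1
  out <- list()
  for (ch in c("dapi", "phalloidin", "runx2")) {
    path <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    if (!file.exists(path)) stop("missing channel file: ", path, call. = FALSE)
    planes <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = c(nrow(planes[[1]]), ncol(planes[[1]]),
                            length(planes)))
    for (p in seq_along(planes)) arr[, , p] <- round(planes[[p]] * max_val)
    out[[ch]] <- arr
  }
  structure(c(out, list(pixel_size = pixel_size, bit_depth = bit_depth)),
            class = "image_stack")
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask Integer label matrix (labels < 65536).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_label_mask <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#'
#' @param path TIFF file.
#' @return Integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- round(tiff::readTIFF(path) * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Write a per-cell table with a metadata header
#'
#' Writes CSV preceded by `#`-prefixed metadata lines recording the texture
#' settings, so a measurement file is self-describing.
#'
#' @param cells Per-cell data frame.
#' @param path Output file.
#' @param params The [texture_params()] used for the measurements.
#' @return Invisibly, `path`.
#' @export
write_cells_csv <- function(cells, path, params = texture_params()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# grey_levels: %d", params$g),
    sprintf("# offset_distance_px: %d", params$d),
    "# entropy_log_base: 2",
    sprintf("# quantization: %s", params$quantization)), con)
  utils::write.csv(cells, con, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell table written by [write_cells_csv()]
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_cells_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
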