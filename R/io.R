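# Calibrated stack / projection containers and TIFF round-trip.

#' Construct a calibrated image stack
#'
#' An `fq_stack` holds a single-channel 3-D intensity array together with its
#' lateral calibration. Slices are stored along the third dimension.
#'
#' @param voxels numeric 3-D array `[row, col, slice]` (a matrix is promoted to
#'   a single-slice stack) of nonnegative intensities.
#' @param pixel_size_xy lateral calibration in micrometres per pixel (> 0).
#' @param z_step axial slice spacing in micrometres (informational; default
#'   0.5, the usual confocal sectioning interval for this application).
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @return an object of class `fq_stack`.
#' @export
image_stack <- function(voxels, pixel_size_xy, z_step = 0.5, bit_depth = 16L) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a [row, col, slice] array")
  if (dim(voxels)[3] < 1L) stop("stack must contain at least one slice")
  if (!is.numeric(pixel_size_xy) || length(pixel_size_xy) != 1L ||
      !is.finite(pixel_size_xy) || pixel_size_xy <= 0)
    stop("'pixel_size_xy' must be a finite positive scalar (um/pixel)")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  vmax <- 2^bit_depth - 1
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > vmax)
    stop(sprintf("intensities must lie in [0, %d] for %d-bit data", vmax, bit_depth))
  structure(
    list(voxels = voxels, pixel_size_xy = pixel_size_xy,
         z_step = z_step, bit_depth = bit_depth),
    class = "fq_stack")
}

#' Construct a calibrated 2-D projection image
#'
#' @param pixels numeric matrix of intensities.
#' @param pixel_size_xy micrometres per pixel (> 0).
#' @return an object of class `fq_projection`.
#' @export
projection_image <- function(pixels, pixel_size_xy) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (!is.numeric(pixel_size_xy) || !is.finite(pixel_size_xy) || pixel_size_xy <= 0)
    stop("'pixel_size_xy' must be a finite positive scalar (um/pixel)")
  structure(list(pixels = pixels, pixel_size_xy = pixel_size_xy),
            class = "fq_projection")
}

#' @export
print.fq_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<fq_stack> %d x %d px, %d slice(s), %d-bit, %.4g um/px, z-step %.3g um\n",
              d[1], d[2], d[3], x$bit_depth, x$pixel_size_xy, x$z_step))
  invisible(x)
}

#' @export
print.fq_projection <- function(x, ...) {
  cat(sprintf("<fq_projection> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_xy,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

.sidecar_path <- function(path) sub("\\.(tif|tiff)$", ".json", path, ignore.case = TRUE)

#' Read a calibrated grayscale TIFF stack
#'
#' Reads a single-channel (grayscale) TIFF or OME-TIFF stack. The lateral
#' calibration is resolved, in order of precedence, from `pixel_size_override`,
#' from a JSON sidecar written by [write_stack()] (same file name with a
#' `.json` extension), or from the file's X/Y resolution tags. Multi-channel
#' (RGB / RGBA) files are rejected rather than collapsed, and anisotropic xy
#' calibration is an error: the downstream length and angle formulas assume
#' square pixels.
#'
#' @param path path to a readable TIFF file.
#' @param pixel_size_override optional micrometres-per-pixel value that takes
#'   precedence over any file metadata.
#' @return an [image_stack()] object.
#' @export
read_stack <- function(path, pixel_size_override = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("multi-channel TIFF not supported: supply a single-channel grayscale stack")
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  if (!all(vapply(pages, function(p) nrow(p) == nr && ncol(p) == nc, logical(1))))
    stop("TIFF pages have inconsistent dimensions")

  bits <- attr(pages[[1]], "bits.per.sample")
  bit_depth <- if (!is.null(bits) && bits <= 8) 8L else 16L

  px <- pixel_size_override
  z_step <- 0.5
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (is.null(px) && !is.null(meta$pixel_size_xy)) px <- as.numeric(meta$pixel_size_xy)
    if (!is.null(meta$z_step)) z_step <- as.numeric(meta$z_step)
  }
  if (is.null(px)) {
    xres <- attr(pages[[1]], "x.resolution")
    yres <- attr(pages[[1]], "y.resolution")
    unit <- attr(pages[[1]], "res.unit")
    if (!is.null(xres) && !is.null(unit) && is.finite(xres) && xres > 0) {
      if (!is.null(yres) && is.finite(yres) && abs(xres - yres) > 1e-6 * xres)
        stop("anisotropic xy calibration is not supported (square pixels assumed)")
      per_um <- switch(unit,
                       "cm" = xres / 1e4, "centimeter" = xres / 1e4,
                       "inch" = xres / 25400, NULL)
      if (!is.null(per_um)) px <- 1 / per_um
    }
  }
  if (is.null(px))
    stop("no pixel-size calibration: file carries no usable metadata ",
         "(sidecar 'pixel_size_xy' or TIFF resolution tags); ",
         "supply 'pixel_size_override' (um/pixel)")

  vox <- array(0, dim = c(nr, nc, length(pages)))
  for (i in seq_along(pages)) vox[, , i] <- pages[[i]]
  image_stack(vox, pixel_size_xy = px, z_step = z_step, bit_depth = bit_depth)
}

#' Write a calibrated stack as a multi-page TIFF plus JSON sidecar
#'
#' Pages are written at the stack's bit depth; the calibration
#' (`pixel_size_xy`, `z_step`, `bit_depth`) goes to a JSON sidecar next to the
#' file, which [read_stack()] picks up automatically.
#'
#' @param stack an [image_stack()] object.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fq_stack"))
  vmax <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$voxels)[3]),
                  function(i) stack$voxels[, , i] / vmax)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  jsonlite::write_json(
    list(pixel_size_xy = stack$pixel_size_xy, z_step = stack$z_step,
         bit_depth = stack$bit_depth),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a projection or mask as a 16-bit grayscale TIFF
#'
#' @param pixels numeric matrix (values clipped to `[0, 65535]`) or a logical
#'   matrix (written as 0 / 65535).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(pixels, path) {
  if (is.logical(pixels)) pixels <- pixels * 65535
  pixels <- pmin(pmax(pixels, 0), 65535)
  tiff::writeTIFF(pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a binary cell mask from TIFF or PNG
#'
#' Zero pixels are background; any nonzero pixel belongs to the cell.
#'
#' @param path path to a single-page grayscale TIFF or PNG.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 2L) stop("mask must be single-channel, got multi-channel image")
    img <- img[, , 1]
  }
  img > 0
}

#' Maximum-intensity projection of a stack
#'
#' Each output pixel is the maximum across slices at that xy position; the
#' lateral calibration is propagated. A stack built from a projection projects
#' to itself (idempotence), and projection commutes with any monotone
#' intensity transform applied uniformly to the stack.
#'
#' @param stack an [image_stack()] object (or a bare 3-D array, in which case
#'   `pixel_size_xy` must be supplied).
#' @param pixel_size_xy calibration, only used when `stack` is a bare array.
#' @param slices optional integer vector restricting the projection to a slice
#'   subset (e.g. top-to-middle acquisitions); default all slices.
#' @return a [projection_image()] object.
#' @export
max_intensity_projection <- function(stack, pixel_size_xy = NULL, slices = NULL) {
  if (inherits(stack, "fq_stack")) {
    vox <- stack$voxels
    px <- stack$pixel_size_xy
  } else {
    vox <- stack
    px <- pixel_size_xy
    if (is.null(px)) stop("'pixel_size_xy' required for a bare array")
    if (is.matrix(vox)) vox <- array(vox, dim = c(dim(vox), 1L))
  }
  ns <- dim(vox)[3]
  if (is.null(ns) || ns < 1L) stop("empty stack: nothing to project")
  if (is.null(slices)) slices <- seq_len(ns)
  if (!all(slices %in% seq_len(ns))) stop("'slices' out of range")
  proj <- Reduce(pmax, lapply(slices, function(s) vox[, , s]))
  projection_image(proj, px)
}
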