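# Cell-region definition: mask handling, moment-based ellipse fit, shape
# classification, and restriction of the skeleton to the cell.

# Second-moment ellipse fit of a binary mask. Angles are counterclockwise
# from the +x (column) axis, rows growing downward, reduced to [0, 180).
.fit_ellipse <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  n <- nrow(w)
  x <- w[, 2]; y <- -w[, 1]          # y up, so CCW angles are standard
  mx <- mean(x); my <- mean(y)
  # 1/12 is the second moment of a unit pixel about its centre
  cxx <- mean((x - mx)^2) + 1 / 12
  cyy <- mean((y - my)^2) + 1 / 12
  cxy <- mean((x - mx) * (y - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L), symmetric = TRUE)
  theta <- (atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi) %% 180
  list(centroid = c(row = -my, col = mx),
       major_px = 4 * sqrt(ev$values[1]),   # full axis of the equivalent ellipse
       minor_px = 4 * sqrt(ev$values[2]),
       theta = theta,
       aspect_ratio = sqrt(ev$values[1] / ev$values[2]),
       area_px = n)
}

# Solidity: mask area over the lattice-point count of the pixel-centre convex
# hull (shoelace area + boundary/2 + 1, Pick's theorem).
.solidity <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) < 3L) return(1)
  x <- w[, 2]; y <- w[, 1]
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  k <- length(h)
  j <- c(2:k, 1L)
  area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  per <- sum(.gcd2(abs(hx[j] - hx), abs(hy[j] - hy)))  # lattice boundary points
  hull_px <- area + per / 2 + 1
  min(1, nrow(w) / hull_px)
}

.gcd2 <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (any(b != 0L)) {
    t <- b
    b <- ifelse(b == 0L, 0L, a %% b)
    a <- t
  }
  pmax(a, 1L)
}

#' Define the cell region from a mask or by automatic segmentation
#'
#' With a mask, the region is taken as given. Without one, an automatic
#' fallback replaces manual segmentation: Gaussian blur (sigma = 5 px), Otsu
#' threshold, largest connected component, hole filling, and binary closing.
#' The region's ellipse is fitted from the mask's second moments; its
#' orientation `theta_protoplast` lies in `[0, 180)`.
#'
#' @param projection a calibrated [projection_image()].
#' @param mask optional logical matrix of the same shape (nonzero = cell).
#' @param convexity_threshold solidity below which the cell is classified as
#'   deformed (default 0.95); see [classify_shape()].
#' @return an object of class `fq_region` with elements `mask`, `centroid`
#'   (row, col), `major_axis` and `minor_axis` (um), `theta_protoplast`
#'   (degrees), `aspect_ratio`, `solidity`, `shape_class`, `area_px`, and
#'   `pixel_size_xy`.
#' @export
load_or_segment_region <- function(projection, mask = NULL,
                                   convexity_threshold = 0.95) {
  stopifnot(inherits(projection, "fq_projection"))
  if (is.null(mask)) {
    M <- projection$pixels
    rng <- diff(range(M))
    if (rng == 0) stop("segmentation failed: constant image")
    norm <- (M - min(M)) / rng
    sm <- .gauss_blur(norm, 5)
    thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
    bw <- sm > thr
    if (!any(bw)) stop("segmentation failed: no foreground after thresholding")
    lab <- .label_mask_components(bw)
    sizes <- tabulate(lab[lab > 0L])
    bw <- lab == which.max(sizes)
    img <- EBImage::fillHull(EBImage::Image(bw * 1))
    img <- EBImage::closing(img, EBImage::makeBrush(5L, "disc"))
    mask <- as.matrix(img) > 0
  } else {
    mask <- mask != 0
    if (!identical(dim(mask), dim(projection$pixels)))
      stop("mask shape does not match the projection")
  }
  if (!any(mask)) stop("segmentation failed: empty cell mask")
  fit <- .fit_ellipse(mask)
  px <- projection$pixel_size_xy
  region <- structure(
    list(mask = mask, centroid = fit$centroid,
         major_axis = fit$major_px * px, minor_axis = fit$minor_px * px,
         theta_protoplast = fit$theta, aspect_ratio = fit$aspect_ratio,
         solidity = .solidity(mask), shape_class = NA_character_,
         area_px = fit$area_px, pixel_size_xy = px),
    class = "fq_region")
  region$shape_class <- classify_shape(region, convexity_threshold)
  region
}

# Dense-mask component labeling (8-connectivity) via EBImage.
.label_mask_components <- function(bw) {
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  matrix(as.integer(as.matrix(lab)), nrow(bw), ncol(bw))
}

#' @export
print.fq_region <- function(x, ...) {
  cat(sprintf(paste0("<fq_region> %s, %d px, axes %.1f x %.1f um, ",
                     "theta %.1f deg, AR %.3f, solidity %.3f\n"),
              x$shape_class, x$area_px, x$major_axis, x$minor_axis,
              x$theta_protoplast, x$aspect_ratio, x$solidity))
  invisible(x)
}

#' Classify the cell shape from its fitted ellipse and solidity
#'
#' A cell is `deformed` (bud-shaped, non-convex outline) when its solidity
#' falls below `convexity_threshold`; otherwise `oval` when the fitted-ellipse
#' aspect ratio exceeds 1.05, else `spherical`. The aspect-ratio boundary is
#' the published classification rule; the solidity rule quantifies the
#' visually defined bud class and is this package's own. Scale-invariant.
#'
#' @param region an `fq_region`.
#' @param convexity_threshold solidity cut for the deformed class
#'   (default 0.95).
#' @return one of `"deformed"`, `"oval"`, `"spherical"`.
#' @export
classify_shape <- function(region, convexity_threshold = 0.95) {
  stopifnot(inherits(region, "fq_region"))
  if (region$solidity < convexity_threshold) return("deformed")
  if (region$aspect_ratio > 1.05) return("oval")
  "spherical"
}

#' Restrict a skeleton to the cell region
#'
#' Skeleton pixels outside the mask are removed, and the pruning rules
#' (branch shaving and small-component deletion, with the skeleton's own
#' parameters) are re-applied so that clipping at the cell boundary cannot
#' leave sub-threshold fragments. Never adds pixels: the skeleton pixel count
#' is non-increasing under masking.
#'
#' @param skel an `fq_skeleton`.
#' @param region an `fq_region` with a mask of the same shape.
#' @return a masked, re-pruned `fq_skeleton`.
#' @export
mask_skeleton <- function(skel, region) {
  stopifnot(inherits(skel, "fq_skeleton"), inherits(region, "fq_region"))
  if (!identical(dim(skel$skeleton), dim(region$mask)))
    stop("skeleton and region shapes do not match")
  prune_skeleton(skel$skeleton & region$mask,
                 shave_len = skel$shave_len, del_len = skel$del_len,
                 reference = skel$reference,
                 pixel_size_xy = skel$pixel_size_xy)
}
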