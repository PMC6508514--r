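# The five configuration metrics and their intermediates, computed from a
# masked one-pixel-wide skeleton and the fitted cell region.

#' Total skeleton length in millimetres
#'
#' The skeleton pixel count (N_cellulose) converted to physical length:
#' `n_pixels * pixel_size_xy (um) / 1000`. An empty skeleton has length 0.
#' A diagonal-corrected variant (diagonal pixel adjacencies weighted by
#' sqrt(2)) is available from [compute_all()] as `total_length_corrected_mm`;
#' it is the better arc-length estimator for oblique fibers, while this raw
#' definition keeps the pixel-count convention.
#'
#' @param skel an `fq_skeleton` with a valid `pixel_size_xy`.
#' @return length in mm.
#' @export
total_length <- function(skel) {
  stopifnot(inherits(skel, "fq_skeleton"))
  if (!is.finite(skel$pixel_size_xy) || skel$pixel_size_xy <= 0)
    stop("skeleton carries no pixel-size calibration")
  sum(skel$skeleton) * skel$pixel_size_xy / 1000
}

#' Mean intensity of skeleton pixels
#'
#' @param skel an `fq_skeleton` with sampled intensities.
#' @return arithmetic mean of skeleton-pixel intensities; `NA` (with
#'   attribute `reason`) for an empty skeleton.
#' @export
mean_intensity <- function(skel) {
  stopifnot(inherits(skel, "fq_skeleton"))
  if (length(skel$intensities) == 0L)
    return(structure(NA_real_, reason = "empty_skeleton"))
  mean(skel$intensities)
}

#' Skewness of the skeleton-pixel intensity distribution
#'
#' Population third standardized moment, a proxy for fibril bundling: a few
#' disproportionately bright (bundled) pixels over many dim single-fiber
#' pixels produce a right tail and a large positive S. Both the SD and the
#' third moment use the population divisor N (no sample-bias correction):
#' `S = (1/N) * sum(((i - mean) / sigma)^3)` with
#' `sigma = sqrt((1/N) * sum((i - mean)^2))`. Invariant under affine
#' intensity maps `i -> a*i + b`, `a > 0`.
#'
#' @param skel an `fq_skeleton`, or a bare numeric vector of intensities.
#' @return S; `NA` with attribute `reason` when fewer than 3 pixels or when
#'   the intensities are constant (sigma = 0).
#' @export
intensity_skewness <- function(skel) {
  x <- if (inherits(skel, "fq_skeleton")) skel$intensities else as.numeric(skel)
  n <- length(x)
  if (n < 3L) return(structure(NA_real_, reason = "too_few_pixels"))
  m <- mean(x)
  sigma <- sqrt(mean((x - m)^2))
  if (sigma == 0) return(structure(NA_real_, reason = "constant_intensity"))
  mean(((x - m) / sigma)^3)
}

# Population SD with divisor N, as used inside the skewness definition.
.population_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Orientation counts of adjacent skeleton pixel pairs
#'
#' Every unordered pair of 8-adjacent skeleton pixels is assigned the axial
#' direction of its connecting vector, which on the square lattice is exactly
#' one of 0, 45, 90 or 135 degrees (counterclockwise from the +x/column axis,
#' mod 180). Each adjacent pair is counted once.
#'
#' @param skel an `fq_skeleton` or a logical matrix.
#' @return named integer vector `c(n0, n45, n90, n135)`.
#' @export
pair_orientation_counts <- function(skel) {
  m <- if (inherits(skel, "fq_skeleton")) skel$skeleton else skel != 0
  M <- m * 1
  # neighbour at (dr, dc) relative to each pixel; each unordered pair appears
  # under exactly one of these four offsets
  n0   <- sum(M * .shift_zero(M, 0L, -1L))   # left neighbour: horizontal pair
  n90  <- sum(M * .shift_zero(M, -1L, 0L))   # up neighbour: vertical pair
  n45  <- sum(M * .shift_zero(M, 1L, -1L))   # down-left: vector (+x, +y) = 45
  n135 <- sum(M * .shift_zero(M, -1L, -1L))  # up-left: vector (+x, -y) = 135
  c(n0 = n0, n45 = n45, n90 = n90, n135 = n135)
}

#' Parallelness of the skeleton
#'
#' `P = (|n0 - n90| + |n45 - n135|) / (n0 + n45 + n90 + n135)`, the normalized
#' contrast between orthogonal adjacent-pair orientation counts; 1 for a
#' perfectly parallel skeleton, 0 for an isotropic one.
#'
#' @param counts a vector as returned by [pair_orientation_counts()], or an
#'   `fq_skeleton`.
#' @return P in `[0, 1]`; `NA` with attribute `reason` when there are no
#'   adjacent pairs.
#' @export
parallelness <- function(counts) {
  if (inherits(counts, "fq_skeleton")) counts <- pair_orientation_counts(counts)
  tot <- sum(counts)
  if (tot < 1) return(structure(NA_real_, reason = "no_pairs"))
  (abs(counts[["n0"]] - counts[["n90"]]) +
      abs(counts[["n45"]] - counts[["n135"]])) / tot
}

#' Axial circular mean of orientations
#'
#' Orientations are doubled (axial data are defined mod 180), averaged as
#' unit vectors with optional weights, and the resultant angle halved and
#' reduced to `[0, 180)`. Equal mass at 10 and 170 degrees therefore averages
#' to 0, not 90.
#'
#' @param angles_deg orientations in degrees.
#' @param weights optional nonnegative weights (default equal).
#' @return mean orientation in `[0, 180)`; `NA` with attribute `reason` when
#'   the doubled resultant length is (numerically) zero, i.e. the orientation
#'   mass is perfectly balanced.
#' @export
axial_mean <- function(angles_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  if (!length(angles_deg) || sum(weights) <= 0)
    return(structure(NA_real_, reason = "no_pairs"))
  th <- 2 * angles_deg * pi / 180
  C <- sum(weights * cos(th)); S <- sum(weights * sin(th))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-9 * sum(weights))
    return(structure(NA_real_, reason = "balanced_orientation"))
  ((atan2(S, C) / 2) * 180 / pi) %% 180
}

#' Mean fiber orientation of the skeleton
#'
#' Axial circular mean over the adjacent-pair orientation classes
#' (0/45/90/135 degrees). Diagonal pairs are weighted by sqrt(2), their
#' physical length on the lattice, which bounds the quantization bias of the
#' four-class direction set to under ~2 degrees at intermediate orientations.
#'
#' @param skel an `fq_skeleton` or a logical matrix.
#' @return mean orientation `theta_cellulose` in `[0, 180)`; `NA` with
#'   attribute `reason` when there are no pairs or the orientation mass is
#'   perfectly balanced.
#' @export
mean_fiber_angle <- function(skel) {
  counts <- pair_orientation_counts(skel)
  if (sum(counts) < 1) return(structure(NA_real_, reason = "no_pairs"))
  axial_mean(c(0, 45, 90, 135),
             weights = counts * c(1, sqrt(2), 1, sqrt(2)))
}

#' Angle between the fiber network and the cell's long axis
#'
#' Piecewise rule on the absolute difference `d = |theta_protoplast -
#' theta_cellulose|`: `d` when `d <= 90`, else `d - 90`. This is the published
#' definition, implemented verbatim; note it differs from the standard axial
#' distance `min(d, 180 - d)` (a 170-degree difference maps to 80, not 10).
#' The standard axial distance is reported alongside by [compute_all()] as
#' `delta_theta_axial`.
#'
#' @param theta_protoplast cell long-axis orientation, degrees in `[0, 180)`.
#' @param theta_cellulose mean fiber orientation, degrees in `[0, 180)`.
#' @return angle in `[0, 90]`.
#' @export
delta_theta <- function(theta_protoplast, theta_cellulose) {
  d <- abs(theta_protoplast - theta_cellulose)
  ifelse(d <= 90, d, d - 90)
}

#' Compute the full metric set for one cell
#'
#' Runs every metric on a masked skeleton and its cell region. Undefined
#' metrics (empty skeleton, constant intensities, no adjacent pairs, balanced
#' orientation) are reported as `NA` with machine-readable reason codes in
#' `missing_reason` -- never as 0, since 0 is a meaningful value for S and P.
#'
#' @param skel an `fq_skeleton`, already restricted to the cell (see
#'   [mask_skeleton()]).
#' @param region the matching `fq_region`.
#' @param cell_id identifier copied into the output (default `"cell"`).
#' @return an object of class `fq_metrics`: a list with `cell_id`,
#'   `shape_class`, `aspect_ratio`, `theta_protoplast`, `n_cellulose`,
#'   `total_length_mm`, `total_length_corrected_mm`, `mean_intensity`,
#'   `sigma`, `stddev_per_mean`, `skewness`, `pair_counts`, `parallelness`,
#'   `theta_cellulose`, `delta_theta`, `delta_theta_axial`, and
#'   `missing_reason`.
#' @export
compute_all <- function(skel, region, cell_id = "cell") {
  stopifnot(inherits(skel, "fq_skeleton"), inherits(region, "fq_region"))
  reasons <- character(0)
  n_px <- sum(skel$skeleton)
  counts <- pair_orientation_counts(skel)
  px <- skel$pixel_size_xy

  tl <- total_length(skel)
  tl_corr <- ((counts[["n0"]] + counts[["n90"]]) +
                sqrt(2) * (counts[["n45"]] + counts[["n135"]])) * px / 1000

  mi <- mean_intensity(skel)
  reasons <- c(reasons, attr(mi, "reason"))
  sk <- intensity_skewness(skel)
  reasons <- c(reasons, attr(sk, "reason"))
  sigma <- if (n_px > 0L) .population_sd(skel$intensities) else NA_real_
  spm <- if (!is.na(mi) && mi > 0) sigma / as.numeric(mi) else NA_real_

  pp <- parallelness(counts)
  reasons <- c(reasons, attr(pp, "reason"))
  tc <- mean_fiber_angle(skel)
  reasons <- c(reasons, attr(tc, "reason"))
  dt <- if (is.na(tc)) NA_real_ else delta_theta(region$theta_protoplast, as.numeric(tc))
  dt_ax <- if (is.na(tc)) NA_real_ else {
    d <- abs(region$theta_protoplast - as.numeric(tc))
    min(d, 180 - d)
  }

  structure(list(
    cell_id = cell_id,
    shape_class = region$shape_class,
    aspect_ratio = region$aspect_ratio,
    theta_protoplast = region$theta_protoplast,
    n_cellulose = n_px,
    total_length_mm = tl,
    total_length_corrected_mm = as.numeric(tl_corr),
    mean_intensity = as.numeric(mi),
    sigma = sigma,
    stddev_per_mean = spm,
    skewness = as.numeric(sk),
    pair_counts = counts,
    parallelness = as.numeric(pp),
    theta_cellulose = as.numeric(tc),
    delta_theta = as.numeric(dt),
    delta_theta_axial = dt_ax,
    missing_reason = paste(unique(reasons), collapse = ";")
  ), class = "fq_metrics")
}

#' One-row data frame for a metric set
#'
#' Columns, in fixed order, follow the measurement naming of the underlying
#' line-feature tooling: `cell_id, shape_class, aspect_ratio,
#' theta_protoplast, i_nPix, total_length_mm, total_length_corrected_mm,
#' i_mean, i_stddevPerMean, i_skewness, n0, n45, n90, n135, a_normAvgRad,
#' a_avgTheta, delta_theta_deg, missing_reason`, where `i_nPix` is the
#' skeleton pixel count, `a_normAvgRad` the parallelness and `a_avgTheta` the
#' mean fiber orientation.
#'
#' @param x an `fq_metrics` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a one-row `data.frame`.
#' @export
as.data.frame.fq_metrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    cell_id = x$cell_id,
    shape_class = x$shape_class,
    aspect_ratio = x$aspect_ratio,
    theta_protoplast = x$theta_protoplast,
    i_nPix = x$n_cellulose,
    total_length_mm = x$total_length_mm,
    total_length_corrected_mm = x$total_length_corrected_mm,
    i_mean = x$mean_intensity,
    i_stddevPerMean = x$stddev_per_mean,
    i_skewness = x$skewness,
    n0 = x$pair_counts[["n0"]],
    n45 = x$pair_counts[["n45"]],
    n90 = x$pair_counts[["n90"]],
    n135 = x$pair_counts[["n135"]],
    a_normAvgRad = x$parallelness,
    a_avgTheta = x$theta_cellulose,
    delta_theta_deg = x$delta_theta,
    missing_reason = x$missing_reason,
    stringsAsFactors = FALSE
  )
}

#' @export
print.fq_metrics <- function(x, ...) {
  cat(sprintf("<fq_metrics> %s [%s]\n", x$cell_id, x$shape_class))
  cat(sprintf("  N = %d px, length %.4f mm (corrected %.4f mm)\n",
              x$n_cellulose, x$total_length_mm, x$total_length_corrected_mm))
  cat(sprintf("  mean intensity %.2f, skewness %.3f\n",
              x$mean_intensity, x$skewness))
  cat(sprintf("  P %.3f, theta_cellulose %.1f, theta_protoplast %.1f, delta_theta %.1f\n",
              x$parallelness, x$theta_cellulose, x$theta_protoplast, x$delta_theta))
  if (nzchar(x$missing_reason)) cat("  missing:", x$missing_reason, "\n")
  invisible(x)
}
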