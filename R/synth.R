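# Ground-truthed synthetic scenes: random fiber networks on a disc-shaped
# cell, rendered with a Gaussian line profile, photon (Poisson) noise and
# Gaussian read noise, emulating Calcofluor-stained fibril networks imaged on
# a 16-bit confocal system.

#' Parameters of a synthetic fibril-network scene
#'
#' Defaults emulate a regenerating protoplast (~35 um across at 0.2 um/px)
#' bearing a moderately dense, partly bundled fibril network imaged on a
#' 16-bit confocal system.
#'
#' @param image_size image side in pixels (square; default 256).
#' @param pixel_size_xy micrometres per pixel (default 0.2).
#' @param cell_axes semi-axes (a, b) of the cell ellipse in pixels
#'   (default c(90, 75)).
#' @param cell_angle orientation of the cell's major axis, degrees CCW from
#'   +x (default 0).
#' @param n_fibers number of fibers (default 60).
#' @param orientation_mode `"uniform"` or `"vonmises"` (axial von Mises via
#'   the doubled-angle construction).
#' @param mu mean fiber orientation in degrees for `"vonmises"` (default 90).
#' @param kappa concentration of the doubled-angle von Mises (default 3;
#'   kappa >= 20 gives an axial SD of roughly 6 degrees).
#' @param bundling_fraction share of fibers snapped onto shared bundle paths
#'   (default 0.2). Bundled fibers are partitioned into shared paths by a
#'   Chinese-restaurant process whose concentration falls as bundling rises,
#'   so bundle thickness has a smooth heavy tail; co-located fibers add their
#'   intensities.
#' @param fiber_intensity base per-fiber line intensity in DN (default 3000).
#' @param bundle_gain intensity multiplier applied to each bundled fiber
#'   (default 1).
#' @param psf_sigma Gaussian line-profile width in pixels (default 1.5).
#' @param noise_model `"poisson-gaussian"` (default) or `"none"`.
#' @param gain_e_per_dn photons per DN for Poisson scaling (default 0.5).
#' @param read_noise_sd Gaussian read noise SD in DN (default 2).
#' @param n_slices slices in the rendered stack; geometry is shared, noise is
#'   independent per slice so the projection path is exercised (default 3).
#' @param fiber_len_range target fiber length range in pixels
#'   (default c(60, 180)).
#' @param step_len polyline step length in pixels (default 4).
#' @param turn_sd per-step heading change SD in degrees (default 4, clamped
#'   to three SDs; 0 gives straight fibers).
#' @param seed RNG seed; `NULL` leaves the RNG state alone. Seeded runs are
#'   reproducible bit-exactly.
#' @return a list of class `fq_scene_params`.
#' @export
scene_params <- function(image_size = 256L, pixel_size_xy = 0.2,
                         cell_axes = c(90, 75), cell_angle = 0,
                         n_fibers = 60L,
                         orientation_mode = c("uniform", "vonmises"),
                         mu = 90, kappa = 3,
                         bundling_fraction = 0.2,
                         fiber_intensity = 3000, bundle_gain = 1,
                         psf_sigma = 1.5,
                         noise_model = c("poisson-gaussian", "none"),
                         gain_e_per_dn = 0.5, read_noise_sd = 2,
                         n_slices = 3L,
                         fiber_len_range = c(60, 180),
                         step_len = 4, turn_sd = 4,
                         seed = NULL) {
  orientation_mode <- match.arg(orientation_mode)
  noise_model <- match.arg(noise_model)
  if (any(cell_axes <= 0)) stop("degenerate cell: both ellipse axes must be > 0")
  if (n_fibers < 0L) stop("'n_fibers' must be >= 0")
  if (bundling_fraction < 0 || bundling_fraction > 1)
    stop("'bundling_fraction' must lie in [0, 1]")
  structure(as.list(environment()), class = "fq_scene_params")
}

# Chinese-restaurant-process partition sizes for n items, concentration
# theta: each item starts a new group with probability theta/(theta+i-1),
# otherwise joins an existing group size-proportionally.
.crp_sizes <- function(n, theta) {
  sizes <- integer(0)
  for (i in seq_len(n)) {
    if (!length(sizes) || runif(1) < theta / (theta + i - 1)) {
      sizes <- c(sizes, 1L)
    } else {
      j <- sample.int(length(sizes), 1L, prob = sizes)
      sizes[j] <- sizes[j] + 1L
    }
  }
  sizes
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy envelope); radians.
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- (sign(runif(1) - 0.5) * acos(f) + mu) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# Axial orientation draw in degrees, [0, 180).
.draw_orientations <- function(n, params) {
  if (params$orientation_mode == "uniform") return(runif(n, 0, 180))
  phi <- .rvonmises(n, (2 * params$mu * pi / 180) %% (2 * pi), params$kappa)
  (phi * 90 / pi) %% 180
}

# Is (row, col) inside the cell ellipse (with a small safety margin)?
.in_ellipse <- function(r, c, params, margin = 0.97) {
  ctr <- (params$image_size + 1) / 2
  x <- c - ctr; y <- -(r - ctr)
  th <- -params$cell_angle * pi / 180
  xr <- x * cos(th) - y * sin(th)
  yr <- x * sin(th) + y * cos(th)
  (xr / (params$cell_axes[1] * margin))^2 +
    (yr / (params$cell_axes[2] * margin))^2 <= 1
}

# Grow one polyline from a random interior point, both directions along the
# drawn orientation, bounded turning, clipped to the cell ellipse.
# `len_scale` shortens the target length (thick bundles are compact).
# Returns a matrix of (row, col) vertices.
.grow_path <- function(theta0, params, len_scale = 1) {
  ctr <- (params$image_size + 1) / 2
  u <- sqrt(runif(1)); phi <- runif(1, 0, 2 * pi)
  xr <- params$cell_axes[1] * 0.9 * u * cos(phi)
  yr <- params$cell_axes[2] * 0.9 * u * sin(phi)
  ca <- params$cell_angle * pi / 180
  x0 <- xr * cos(ca) - yr * sin(ca)
  y0 <- xr * sin(ca) + yr * cos(ca)
  start <- c(ctr - y0, ctr + x0)                    # (row, col)
  target_len <- len_scale * runif(1, params$fiber_len_range[1], params$fiber_len_range[2])
  target_len <- max(target_len, 3 * params$step_len)
  n_steps <- max(1L, round(target_len / params$step_len))
  half <- c(ceiling(n_steps / 2), floor(n_steps / 2))
  arms <- list()
  for (side in 1:2) {
    heading <- theta0 + if (side == 1) 0 else 180
    pts <- matrix(start, nrow = 1L)
    p <- start
    for (k in seq_len(half[side])) {
      turn <- rnorm(1, 0, params$turn_sd)
      turn <- max(min(turn, 3 * params$turn_sd), -3 * params$turn_sd)
      heading <- heading + turn
      th <- heading * pi / 180
      q <- p + params$step_len * c(-sin(th), cos(th))  # rows grow downward
      if (!.in_ellipse(q[1], q[2], params)) break
      pts <- rbind(pts, q)
      p <- q
    }
    arms[[side]] <- pts
  }
  # join: reversed arm 2 + arm 1 (shared start kept once)
  a2 <- arms[[2]]
  if (nrow(a2) > 1L) rbind(a2[nrow(a2):2, , drop = FALSE], arms[[1]])
  else arms[[1]]
}

# Bresenham raster of one segment; returns (row, col) integer matrix.
.raster_segment <- function(r0, c0, r1, c1) {
  r0 <- round(r0); c0 <- round(c0); r1 <- round(r1); c1 <- round(c1)
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out
}

# Raster of a full polyline (deduplicated joints).
.raster_polyline <- function(pts) {
  if (nrow(pts) < 2L)
    return(matrix(round(pts[1, ]), 1L, 2L))
  segs <- lapply(seq_len(nrow(pts) - 1L), function(i)
    .raster_segment(pts[i, 1], pts[i, 2], pts[i + 1, 1], pts[i + 1, 2]))
  px <- do.call(rbind, segs)
  px[!duplicated(px), , drop = FALSE]
}

.polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Length-weighted axial mean orientation of a polyline's segments (degrees).
.polyline_segments <- function(pts) {
  if (nrow(pts) < 2L) return(NULL)
  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  ang <- (atan2(-d[, 1], d[, 2]) * 180 / pi) %% 180   # y up = -row
  len <- sqrt(rowSums(d^2))
  cbind(angle = ang, length = len)
}

#' Generate one ground-truthed synthetic scene
#'
#' Fibers are smooth random polylines clipped to the cell ellipse; a
#' `bundling_fraction` share of them is snapped onto shared bundle paths with
#' additive intensity (bundles appear as disproportionately bright threads).
#' The ideal image stamps each path's total intensity on its Bresenham raster,
#' spreads it with a Gaussian line profile (`psf_sigma`), and each slice adds
#' independent Poisson + Gaussian read noise. Ground truth (polylines,
#' centerline raster, analytic arc length of the distinct rendered paths, and
#' length-weighted mean orientation) is emitted alongside.
#'
#' @param params a [scene_params()] object.
#' @return an object of class `fq_scene`: list with `stack` (an
#'   [image_stack()]), `truth_fibers` (per-fiber list: polyline, orientation,
#'   bundle id), `truth_skeleton` (logical matrix), `truth_total_length`
#'   (mm, arc length of distinct rendered centerlines),
#'   `truth_mean_angle` (degrees), and `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "fq_scene_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_fibers
  sz <- params$image_size

  n_bundled <- round(params$bundling_fraction * n)
  n_single <- n - n_bundled
  # Bundled fibers are partitioned into shared paths by a Chinese-restaurant
  # process whose concentration falls as bundling rises, giving a smooth
  # heavy-tailed bundle-size distribution (many 2-3-fiber bundles, rare thick
  # ones) rather than a bimodal dim/bright split; this is what makes the
  # intensity skewness grow with the bundling fraction the way bundling
  # proxies behave on real networks.
  sizes <- if (n_bundled > 0L)
    .crp_sizes(n_bundled, 6 * (1 - params$bundling_fraction) /
                 max(params$bundling_fraction, 1e-9)) else integer(0)
  n_bundle_paths <- length(sizes)

  # distinct geometric paths: one per single fiber plus the shared bundles;
  # a bundle of k fibers is drawn at 1/sqrt(k) of the single-fiber length --
  # thick bundles are short, compact structures, which keeps the bright-pixel
  # share of the image small while the bundle amplitude grows
  n_paths <- n_single + n_bundle_paths
  len_scale <- c(rep(1, n_single), 1 / sqrt(pmax(sizes, 1)))
  thetas <- .draw_orientations(max(n_paths, 1L), params)
  paths <- lapply(seq_len(n_paths), function(i)
    .grow_path(thetas[i], params, len_scale[i]))

  fiber_path <- c(seq_len(n_single),
                  if (n_bundled > 0L) n_single + rep(seq_along(sizes), sizes))
  fiber_bundle <- c(rep(NA_integer_, n_single),
                    if (n_bundled > 0L) rep(seq_along(sizes), sizes))
  fiber_gain <- ifelse(is.na(fiber_bundle), 1, params$bundle_gain)
  fiber_int <- if (n > 0L)
    params$fiber_intensity * fiber_gain * exp(rnorm(n, 0, 0.15)) else numeric(0)

  ideal <- matrix(0, sz, sz)
  truth_mask <- matrix(FALSE, sz, sz)
  if (n_paths > 0L && n > 0L) {
    path_int <- vapply(seq_len(n_paths), function(p)
      sum(fiber_int[fiber_path == p]), numeric(1))
    for (p in seq_len(n_paths)) {
      if (path_int[p] <= 0) next
      px <- .raster_polyline(paths[[p]])
      keep <- px[, 1] >= 1 & px[, 1] <= sz & px[, 2] >= 1 & px[, 2] <= sz
      px <- px[keep, , drop = FALSE]
      lin <- (px[, 2] - 1L) * sz + px[, 1]
      ideal[lin] <- ideal[lin] + path_int[p]
      truth_mask[lin] <- TRUE
    }
    ideal <- pmax(.gauss_blur(ideal, params$psf_sigma), 0)
  }

  rendered_paths <- if (n > 0L)
    which(tabulate(fiber_path, nbins = n_paths) > 0L) else integer(0)
  truth_len_px <- sum(vapply(paths[rendered_paths], .polyline_length, numeric(1)))

  segs <- do.call(rbind, lapply(rendered_paths, function(p)
    .polyline_segments(paths[[p]])))
  truth_angle <- if (is.null(segs) || nrow(segs) == 0L) NA_real_
                 else as.numeric(axial_mean(segs[, "angle"], segs[, "length"]))

  vmax <- 65535
  vox <- array(0, dim = c(sz, sz, params$n_slices))
  for (s in seq_len(params$n_slices)) {
    sl <- if (params$noise_model == "none") ideal else {
      photons <- rpois(length(ideal), ideal * params$gain_e_per_dn)
      photons / params$gain_e_per_dn + rnorm(length(ideal), 0, params$read_noise_sd)
    }
    vox[, , s] <- matrix(pmin(pmax(round(sl), 0), vmax), sz, sz)
  }

  truth_fibers <- lapply(seq_len(n), function(i) list(
    polyline = paths[[fiber_path[i]]],
    orientation = thetas[fiber_path[i]],
    bundle_id = fiber_bundle[i],
    intensity = fiber_int[i]))

  structure(list(
    stack = image_stack(vox, pixel_size_xy = params$pixel_size_xy,
                        bit_depth = 16L),
    truth_fibers = truth_fibers,
    truth_skeleton = truth_mask,
    truth_total_length = truth_len_px * params$pixel_size_xy / 1000,
    truth_mean_angle = truth_angle,
    params = params
  ), class = "fq_scene")
}

#' @export
print.fq_scene <- function(x, ...) {
  cat(sprintf("<fq_scene> %d fibers, truth length %.4f mm, mean angle %.1f deg\n",
              length(x$truth_fibers), x$truth_total_length, x$truth_mean_angle))
  invisible(x)
}

#' Generate the control / depolymerized / stabilized scene trio
#'
#' Emulates the two microtubule-drug perturbations as synthetic regimes:
#' `control` uses `base` unchanged; `oryzalin` (depolymerization-like) keeps
#' 40% of the fibers and concentrates their orientation near the cell's long
#' axis (lower angle to the long axis); `taxol` (stabilization-like) raises
#' the bundling fraction to 0.75 and keeps 60% of the fibers, so fewer,
#' brighter threads are rendered.
#'
#' @param base a [scene_params()] object for the control condition.
#' @param seed optional seed applied to every regime (the same seed, so
#'   regimes differ only through their parameters).
#' @return named list of `fq_scene` objects (`control`, `oryzalin`, `taxol`),
#'   each carrying a `regime` element.
#' @export
generate_regimes <- function(base = scene_params(), seed = NULL) {
  params <- regime_params(base, seed)
  scenes <- lapply(names(params), function(nm) {
    sc <- generate_scene(params[[nm]])
    sc$regime <- nm
    sc
  })
  names(scenes) <- names(params)
  scenes
}

#' Per-regime scene parameters
#'
#' The parameter trio behind [generate_regimes()]; see there for the regime
#' definitions.
#'
#' @inheritParams generate_regimes
#' @return named list of `fq_scene_params`.
#' @export
regime_params <- function(base = scene_params(), seed = NULL) {
  stopifnot(inherits(base, "fq_scene_params"))
  tweak <- function(p, ...) {
    upd <- list(...)
    for (nm in names(upd)) p[[nm]] <- upd[[nm]]
    if (!is.null(seed)) p$seed <- seed
    p
  }
  list(
    control  = tweak(base),
    oryzalin = tweak(base, n_fibers = as.integer(round(0.4 * base$n_fibers)),
                     orientation_mode = "vonmises",
                     mu = base$cell_angle + 30, kappa = max(base$kappa, 4)),
    taxol    = tweak(base, n_fibers = as.integer(round(0.6 * base$n_fibers)),
                     bundling_fraction = 0.75)
  )
}

#' Do a scene's fiber centerlines keep a minimum pairwise gap?
#'
#' `TRUE` when no two distinct fiber paths come within `gap` pixels of each
#' other (chebyshev distance on the rasterized centerlines). Used to select
#' non-overlapping-fiber scenes for length-recovery validation, where fiber
#' crossings would confound the comparison between measured skeleton length
#' and analytic ground truth.
#'
#' @param scene an `fq_scene`.
#' @param gap minimum separation in pixels (default 2).
#' @return logical scalar.
#' @export
scene_paths_disjoint <- function(scene, gap = 2L) {
  stopifnot(inherits(scene, "fq_scene"))
  sz <- nrow(scene$truth_skeleton)
  acc <- matrix(FALSE, sz, sz)
  paths <- unique(lapply(scene$truth_fibers, function(f) f$polyline))
  for (p in paths) {
    px <- .raster_polyline(p)
    keep <- px[, 1] >= 1 & px[, 1] <= sz & px[, 2] >= 1 & px[, 2] <= sz
    px <- px[keep, , drop = FALSE]
    m <- matrix(FALSE, sz, sz)
    m[cbind(px[, 1], px[, 2])] <- TRUE
    big <- m
    for (g in seq_len(gap)) big <- .dilate3(big * 1) > 0
    if (any(acc & big)) return(FALSE)
    acc <- acc | m
  }
  TRUE
}

#' Write a scene to disk (stack TIFF + sidecar, truth skeleton TIFF, truth JSON)
#'
#' @param scene an `fq_scene`.
#' @param dir output directory (created if needed).
#' @param name file stem (default `"scene"`).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  stopifnot(inherits(scene, "fq_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$stack, file.path(dir, paste0(name, ".tif")))
  write_image_tiff(scene$truth_skeleton,
                   file.path(dir, paste0(name, "_truth_skeleton.tif")))
  jsonlite::write_json(
    list(truth_total_length_mm = scene$truth_total_length,
         truth_mean_angle_deg = scene$truth_mean_angle,
         n_fibers = length(scene$truth_fibers),
         pixel_size_xy = scene$params$pixel_size_xy),
    file.path(dir, paste0(name, "_truth.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
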