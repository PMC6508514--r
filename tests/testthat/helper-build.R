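# Small constructors for hand-built fixtures.

mask_from_pixels <- function(px, nr = 20L, nc = 20L) {
  m <- matrix(FALSE, nr, nc)
  m[cbind(px[, 1], px[, 2])] <- TRUE
  m
}

# A skeleton object directly from a mask and intensity vector, bypassing
# extraction (for metric-level tests).
skeleton_from_mask <- function(mask, intensities = NULL, pixel_size = 0.2) {
  ref <- matrix(0, nrow(mask), ncol(mask))
  if (!is.null(intensities)) ref[mask] <- intensities
  prune_skeleton(mask, shave_len = 0L, del_len = 0L, reference = ref,
                 pixel_size_xy = pixel_size)
}

# Filled-ellipse mask: semi-axes (a, b) px, orientation deg, centred.
ellipse_mask <- function(nr, nc, a, b, theta = 0, centre = NULL) {
  if (is.null(centre)) centre <- c((nr + 1) / 2, (nc + 1) / 2)
  rc <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  x <- rc$c - centre[2]; y <- -(rc$r - centre[1])
  th <- -theta * pi / 180
  xr <- x * cos(th) - y * sin(th)
  yr <- x * sin(th) + y * cos(th)
  matrix((xr / a)^2 + (yr / b)^2 <= 1, nr, nc)
}

rotate90 <- function(M) t(M)[, nrow(M):1, drop = FALSE]

# Recall of a's pixels against b at 1-px tolerance (fraction of TRUE pixels
# of a within the 8-neighbourhood of some TRUE pixel of b).
coverage_1px <- function(a, b) {
  near <- b
  nr <- nrow(b); nc <- ncol(b)
  shift0 <- function(M, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr); cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- M[rs - dr, cs - dc]
    out
  }
  for (dr in -1:1) for (dc in -1:1) if (dr || dc) near <- near | shift0(b, dr, dc)
  if (!any(a)) return(NA_real_)
  mean(near[a])
}
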