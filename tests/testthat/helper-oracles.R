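# Independent brute-force reference implementations used as oracles. These
# are written as literal loops over pixels/pairs, deliberately sharing no
# code with the package internals.

oracle_mip <- function(vox) {
  d <- dim(vox)
  out <- matrix(-Inf, d[1], d[2])
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) for (s in seq_len(d[3]))
    out[r, c] <- max(out[r, c], vox[r, c, s])
  out
}

oracle_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sigma <- sqrt(sum((x - m)^2) / n)
  total <- 0
  for (i in seq_len(n)) total <- total + ((x[i] - m) / sigma)^3
  total / n
}

oracle_pair_counts <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  counts <- c(n0 = 0L, n45 = 0L, n90 = 0L, n135 = 0L)
  n <- nrow(w)
  if (n < 2L) return(counts)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dr <- w[j, 1] - w[i, 1]; dc <- w[j, 2] - w[i, 2]
    if (max(abs(dr), abs(dc)) != 1L) next
    ang <- (atan2(-dr, dc) * 180 / pi) %% 180
    key <- paste0("n", round(ang))
    counts[key] <- counts[key] + 1L
  }
  counts
}

oracle_parallelness <- function(counts) {
  (abs(counts[["n0"]] - counts[["n90"]]) + abs(counts[["n45"]] - counts[["n135"]])) /
    sum(counts)
}

oracle_delta_theta <- function(tp, tc) {
  d <- abs(tp - tc)
  if (d <= 90) d else d - 90
}

# Exhaustive mean line response for every pixel and direction (replicated
# borders, nearest-pixel sampling).
oracle_line_response <- function(img, len, angles) {
  nr <- nrow(img); nc <- ncol(img)
  half <- (len - 1) / 2
  out <- array(NA_real_, c(nr, nc, length(angles)))
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      acc <- 0
      for (k in -half:half) {
        rr <- min(max(r + round(-k * sin(th)), 1), nr)
        cc <- min(max(c + round(k * cos(th)), 1), nc)
        acc <- acc + img[rr, cc]
      }
      out[r, c, a] <- acc / len
    }
  }
  out
}

# Literal-loop shave-then-delete on an already thin mask (8-connectivity).
oracle_prune <- function(mask, shave_len, del_len) {
  nbrs <- function(m, r, c) {
    out <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) && m[rr, cc])
        out <- rbind(out, c(rr, cc))
    }
    out
  }
  deg <- function(m, r, c) { x <- nbrs(m, r, c); if (is.null(x)) 0L else nrow(x) }
  # iterated shaving
  repeat {
    w <- which(mask, arr.ind = TRUE)
    remove <- NULL
    for (i in seq_len(nrow(w))) {
      if (deg(mask, w[i, 1], w[i, 2]) > 1L) next
      path <- NULL
      cur <- w[i, ]
      reached_junction <- FALSE
      repeat {
        if (deg(mask, cur[1], cur[2]) >= 3L) { reached_junction <- TRUE; break }
        path <- rbind(path, cur)
        if (nrow(path) > shave_len) break
        nb <- nbrs(mask, cur[1], cur[2])
        if (is.null(nb)) break
        keep <- rep(TRUE, nrow(nb))
        for (j in seq_len(nrow(nb)))
          for (q in seq_len(nrow(path)))
            if (all(nb[j, ] == path[q, ])) keep[j] <- FALSE
        nb <- nb[keep, , drop = FALSE]
        if (!nrow(nb)) break
        cur <- nb[1, ]
      }
      if (reached_junction && !is.null(path) && nrow(path) <= shave_len) {
        remove <- rbind(remove, path)
        # junction absorbed when its remaining neighbours are one cluster
        nbJ <- nbrs(mask, cur[1], cur[2])
        keep <- rep(TRUE, nrow(nbJ))
        for (j in seq_len(nrow(nbJ)))
          for (q in seq_len(nrow(path)))
            if (all(nbJ[j, ] == path[q, ])) keep[j] <- FALSE
        nbJ <- nbJ[keep, , drop = FALSE]
        if (nrow(path) < shave_len && nrow(nbJ) >= 2L) {
          cl <- seq_len(nrow(nbJ))
          repeat {
            done <- TRUE
            for (a in seq_len(nrow(nbJ))) for (b in seq_len(nrow(nbJ)))
              if (cl[a] != cl[b] && max(abs(nbJ[a, ] - nbJ[b, ])) <= 1L) {
                cl[cl == cl[b]] <- cl[a]; done <- FALSE
              }
            if (done) break
          }
          if (length(unique(cl)) == 1L) remove <- rbind(remove, cur)
        }
      }
    }
    if (is.null(remove)) break
    changed <- FALSE
    for (i in seq_len(nrow(remove))) {
      if (mask[remove[i, 1], remove[i, 2]]) { mask[remove[i, 1], remove[i, 2]] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  # delete small components (always below 2 px)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0L) next
    nextlab <- nextlab + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (lab[j] > 0L) next
      lab[j] <- nextlab
      r <- ((j - 1L) %% nrow(mask)) + 1L; c <- ((j - 1L) %/% nrow(mask)) + 1L
      nb <- nbrs(mask, r, c)
      if (!is.null(nb)) for (q in seq_len(nrow(nb))) {
        k <- (nb[q, 2] - 1L) * nrow(mask) + nb[q, 1]
        if (lab[k] == 0L) queue <- c(queue, k)
      }
    }
  }
  if (nextlab > 0L) {
    sizes <- tabulate(lab[lab > 0L], nextlab)
    for (l in which(sizes <= max(del_len, 1L))) mask[lab == l] <- FALSE
  }
  mask
}

# Exact two-sided Mann-Whitney p-value by enumeration of all rank splits.
oracle_mw_exact_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(ix) sum(rk[ix]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
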