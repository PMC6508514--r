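# Internal binary-skeleton topology helpers: Zhang-Suen thinning, terminal
# branch shaving, small-component deletion, and 8-connected labeling. Pixel
# adjacency is 8-connectivity throughout.

# Zhang-Suen thinning to one-pixel width, followed by removal of residual
# 2x2 foreground blocks so that no skeleton pixel sits in a fully-foreground
# 2x2 neighbourhood.
.thin_mask <- function(mask, reduce = TRUE) {
  M <- mask * 1
  if (!any(M > 0)) return(mask & FALSE)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- .shift_zero(M, -1L, 0L);  p3 <- .shift_zero(M, -1L, 1L)
      p4 <- .shift_zero(M, 0L, 1L);   p5 <- .shift_zero(M, 1L, 1L)
      p6 <- .shift_zero(M, 1L, 0L);   p7 <- .shift_zero(M, 1L, -1L)
      p8 <- .shift_zero(M, 0L, -1L);  p9 <- .shift_zero(M, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ring <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- 0
      for (i in 1:8) A <- A + (ring[[i]] == 0 & ring[[i + 1]] == 1)
      cnd <- if (sub == 1) (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
             else          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      del <- M == 1 & B >= 2 & B <= 6 & A == 1 & cnd
      if (any(del)) { M[del] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  # residual 2x2 blocks: drop the top-left corner of each until none remain
  repeat {
    q <- M == 1 & .shift_zero(M, 0L, 1L) == 1 &
      .shift_zero(M, 1L, 0L) == 1 & .shift_zero(M, 1L, 1L) == 1
    if (!any(q)) break
    M[q] <- 0
  }
  if (reduce) .remove_staircase_corners(M == 1) else M == 1
}

# Redundant-pixel reduction: a pixel with at least two foreground neighbours
# whose neighbourhood remains a single 8-connected cluster without it is
# redundant -- removing it preserves connectivity while straightening the
# staircases and domino runs that Zhang-Suen thinning leaves on oblique
# lines. Endpoints (one neighbour) and junctions (disconnected neighbour
# clusters) are never touched. Processed sequentially in column-major order
# for determinism, iterated to a fixed point.
.remove_staircase_corners <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # offsets of the 3x3 box positions (1..9, column-major, centre = 5)
  box_dr <- rep(-1:1, 3); box_dc <- rep(-1:1, each = 3)
  repeat {
    removed <- FALSE
    for (i in which(mask)) {
      r <- ((i - 1L) %% nr) + 1L
      c <- ((i - 1L) %/% nr) + 1L
      if (r < 2L || r > nr - 1L || c < 2L || c > nc - 1L) next
      nb <- which(mask[(r - 1L):(r + 1L), (c - 1L):(c + 1L)])
      nb <- nb[nb != 5L]
      if (length(nb) < 2L) next
      # single-linkage clustering of the neighbours within the 3x3 box
      dr <- box_dr[nb]; dc <- box_dc[nb]
      comp <- seq_along(nb)
      repeat {
        merged <- FALSE
        for (a in seq_along(nb)) for (b in seq_along(nb)) {
          if (comp[a] != comp[b] &&
              abs(dr[a] - dr[b]) <= 1L && abs(dc[a] - dc[b]) <= 1L) {
            comp[comp == comp[b]] <- comp[a]
            merged <- TRUE
          }
        }
        if (!merged) break
      }
      if (length(unique(comp)) == 1L) {
        mask[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  mask
}

# 8-neighbour offsets; the first four generate each unordered adjacency once.
.half_offsets <- cbind(dr = c(0L, 1L, -1L, 1L), dc = c(1L, 0L, 1L, 1L))
.all_offsets <- rbind(.half_offsets, -.half_offsets)

# igraph over skeleton pixels; vertex i corresponds to which(mask)[i]
# (column-major linear indices).
.skel_graph <- function(mask) {
  idx <- which(mask)
  n <- length(idx)
  pos <- integer(length(mask))
  pos[idx] <- seq_len(n)
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  ea <- integer(0); eb <- integer(0)
  for (i in seq_len(nrow(.half_offsets))) {
    rr <- r + .half_offsets[i, 1L]; cc <- c + .half_offsets[i, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(mask)
    nb <- integer(n)
    nb[ok] <- pos[(cc[ok] - 1L) * nr + rr[ok]]
    has <- nb > 0L
    ea <- c(ea, seq_len(n)[has]); eb <- c(eb, nb[has])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(ea)) g <- igraph::add_edges(g, rbind(ea, eb))
  g
}

# One pass of terminal-branch shaving: from every endpoint (degree <= 1),
# walk along the chain; if a junction (degree >= 3) is reached within
# `shave_len` pixels, remove the walked branch (junction excluded). Chains
# that end at another endpoint are whole components and are left for the
# component-deletion rule.
.shave_once <- function(mask, shave_len) {
  if (shave_len <= 0L || !any(mask)) return(mask)
  idx <- which(mask)
  n <- length(idx)
  nr <- nrow(mask)
  pr <- ((idx - 1L) %% nr) + 1L
  pc <- ((idx - 1L) %/% nr) + 1L
  g <- .skel_graph(mask)
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  eps <- which(deg <= 1L)
  if (!length(eps)) return(mask)
  drop <- logical(n)
  for (e in eps) {
    path <- integer(0)
    cur <- e; prev <- 0L
    ok <- FALSE
    repeat {
      if (deg[cur] >= 3L) { ok <- TRUE; break }   # reached a junction
      path <- c(path, cur)
      if (length(path) > shave_len) break          # branch too long to shave
      nb <- setdiff(as.integer(adj[[cur]]), c(prev, path))
      if (!length(nb)) break                       # bare path / isolated chain
      prev <- cur
      cur <- nb[1L]
    }
    if (ok && length(path) <= shave_len) {
      drop[path] <- TRUE
      # absorb the junction pixel itself when, without the branch, its
      # remaining neighbours still form one 8-connected cluster (a spur base
      # diagonally brushing a line); arms of a true crossing stay apart
      rest <- setdiff(as.integer(adj[[cur]]), path)
      if (length(path) < shave_len && length(rest) >= 2L &&
          .one_cluster(pr[rest], pc[rest]))
        drop[cur] <- TRUE
    }
  }
  if (!any(drop)) return(mask)
  out <- mask
  out[idx[drop]] <- FALSE
  out
}

# Are the given pixels a single 8-connected cluster (single linkage)?
.one_cluster <- function(r, c) {
  comp <- seq_along(r)
  repeat {
    merged <- FALSE
    for (a in seq_along(r)) for (b in seq_along(r)) {
      if (comp[a] != comp[b] &&
          abs(r[a] - r[b]) <= 1L && abs(c[a] - c[b]) <= 1L) {
        comp[comp == comp[b]] <- comp[a]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  length(unique(comp)) == 1L
}

# Delete 8-connected components of size <= del_len pixels; single-pixel
# components are always deleted.
.delete_small <- function(mask, del_len) {
  if (!any(mask)) return(mask)
  g <- .skel_graph(mask)
  comp <- igraph::components(g)
  small <- comp$csize[comp$membership] <= max(del_len, 1L)
  if (!any(small)) return(mask)
  out <- mask
  out[which(mask)[small]] <- FALSE
  out
}

# Integer component labels (0 = background), 8-connectivity.
.label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(lab)
  g <- .skel_graph(mask)
  comp <- igraph::components(g)
  lab[which(mask)] <- as.integer(comp$membership)
  lab
}
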