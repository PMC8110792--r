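# Binary skeletonization by Zhang-Suen thinning, vectorized over the
# whole matrix with shifted copies.  Produces an 8-connected, one-pixel
# skeleton; used for filopodium extraction.

shift_mat <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(FALSE, nx, ny)
  xs <- seq_len(nx); ys <- seq_len(ny)
  sx <- xs + dx; sy <- ys + dy
  okx <- sx >= 1L & sx <= nx; oky <- sy >= 1L & sy <= ny
  out[xs[okx], ys[oky]] <- m[sx[okx], sy[oky]]
  out
}

# Neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW);
# y increases downward so "north" is dy = -1.
zs_neighbours <- function(m) {
  list(
    p2 = shift_mat(m, 0L, -1L), p3 = shift_mat(m, 1L, -1L),
    p4 = shift_mat(m, 1L, 0L),  p5 = shift_mat(m, 1L, 1L),
    p6 = shift_mat(m, 0L, 1L),  p7 = shift_mat(m, -1L, 1L),
    p8 = shift_mat(m, -1L, 0L), p9 = shift_mat(m, -1L, -1L)
  )
}

thin_mask <- function(mask, max_iter = 1000L) {
  m <- mask
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- zs_neighbours(m)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqn <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9,
                   nb$p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (!seqn[[i]] & seqn[[i + 1L]])
      if (sub == 1L) {
        cond <- m & B >= 2 & B <= 6 & A == 1L &
          !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1L &
          !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Number of 8-connected neighbours of each skeleton pixel.
neighbour_count <- function(m) {
  nb <- zs_neighbours(m)
  (nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9) * m
}

# Crossing number: 0->1 transitions around the 8-neighbourhood ring.
# 1 = path endpoint, 2 = path interior (including staircase elbows),
# >= 3 = true branch point.
crossing_number <- function(m) {
  nb <- zs_neighbours(m)
  seqn <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9,
               nb$p2)
  A <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) A <- A + (!seqn[[i]] & seqn[[i + 1L]])
  A * m
}

# Geodesic length of a path-like skeleton branch in micrometres: the
# graph diameter under 8-connected moves (orthogonal steps cost 1,
# diagonal steps sqrt(2)), found by a double Dijkstra sweep.  Summing raw
# adjacencies would double-count staircase elbows, where a pixel is both
# orthogonally and diagonally adjacent to the path.
skeleton_length_um <- function(m, scale) {
  idx <- which(m)
  np <- length(idx)
  if (np < 2L) return(0)
  nx <- nrow(m)
  px <- (idx - 1L) %% nx + 1L
  py <- (idx - 1L) %/% nx + 1L
  dx <- outer(px, px, `-`); dy <- outer(py, py, `-`)
  adj <- abs(dx) <= 1L & abs(dy) <= 1L
  w <- matrix(Inf, np, np)
  w[adj & abs(dx) + abs(dy) == 1L] <- 1
  w[adj & abs(dx) == 1L & abs(dy) == 1L] <- sqrt(2)
  diag(w) <- 0
  dijkstra <- function(src) {
    dist <- rep(Inf, np); dist[src] <- 0
    done <- logical(np)
    for (i in seq_len(np)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      dist <- pmin(dist, dist[u] + w[u, ])
    }
    dist
  }
  d1 <- dijkstra(1L)
  d1[!is.finite(d1)] <- -1
  a <- which.max(d1)
  d2 <- dijkstra(a)
  max(d2[is.finite(d2)]) * scale
}

# 3x3 majority vote: smooths single-pixel notches and protrusions on a
# binary mask without eroding 2-px-wide ridges.
majority_smooth <- function(m) {
  s <- m * 1L
  tot <- s
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    tot <- tot + shift_mat(m, dx, dy)
  }
  tot >= 5L
}

# Skeletonize a mask and decompose it into branches, iteratively pruning
# endpoint spurs shorter than `prune_um` (skeletonization artefacts of
# ragged mask edges) and re-thinning so pruned junctions fuse back into
# their parent branch.
skeleton_branches <- function(mask, scale, prune_um = 0.8,
                              max_prune_iter = 3L) {
  skel <- thin_mask(majority_smooth(mask) | thin_mask(mask))
  for (it in seq_len(max_prune_iter)) {
    A <- crossing_number(skel)
    junctions <- skel & A >= 3L
    if (!any(junctions)) break
    branches <- label8(skel & !junctions)
    endpoints <- skel & A == 1L
    removed <- FALSE
    for (b in seq_len(max(branches))) {
      bm <- branches == b
      if (!any(bm & endpoints)) next
      if (skeleton_length_um(bm, scale) < prune_um) {
        skel[bm] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
    skel <- thin_mask(skel)
  }
  A <- crossing_number(skel)
  junctions <- skel & A >= 3L
  list(skel = skel, junctions = junctions,
       branches = label8(skel & !junctions),
       endpoints = skel & A == 1L)
}
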