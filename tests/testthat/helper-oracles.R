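# Independent reference implementations ("oracles") used to verify the
# package's vectorized/compiled code paths. These favor clarity over speed
# and share no code with the package internals.

# brute-force cube sum of `arr` over the (2r+1)^3 box centered at (z,y,x)
oracle_box_sum <- function(arr, center, r) {
  z <- center[1L]; y <- center[2L]; x <- center[3L]
  sum(arr[(z - r):(z + r), (y - r):(y + r), (x - r):(x + r)])
}

# flood fill of a binary array from seed voxels: plain frontier BFS over
# explicit neighbor offsets
oracle_flood_fill <- function(bin, seeds, connectivity = 26L) {
  dm <- dim(bin)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1L, ]
  visited <- array(FALSE, dm)
  out <- array(0L, dm)
  frontier <- list()
  seeds <- rbind(seeds)
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (bin[s[1L], s[2L], s[3L]] == 1L && !visited[s[1L], s[2L], s[3L]]) {
      visited[s[1L], s[2L], s[3L]] <- TRUE
      out[s[1L], s[2L], s[3L]] <- 1L
      frontier[[length(frontier) + 1L]] <- s
    }
  }
  while (length(frontier) > 0L) {
    cur <- frontier[[length(frontier)]]
    frontier[[length(frontier)]] <- NULL
    for (k in seq_len(nrow(offs))) {
      nb <- cur + c(offs$dz[k], offs$dy[k], offs$dx[k])
      if (any(nb < 1L) || any(nb > dm)) next
      if (visited[nb[1L], nb[2L], nb[3L]]) next
      if (bin[nb[1L], nb[2L], nb[3L]] == 1L) {
        visited[nb[1L], nb[2L], nb[3L]] <- TRUE
        out[nb[1L], nb[2L], nb[3L]] <- 1L
        frontier[[length(frontier) + 1L]] <- nb
      }
    }
  }
  out
}

# connected components via igraph (independent of the package's BFS)
oracle_components <- function(bin, connectivity = 26L) {
  dm <- dim(bin)
  fg <- which(bin == 1L)
  if (length(fg) == 0L) return(array(0L, dm))
  pos <- arrayInd(fg, dm)
  id_of <- array(0L, dm)
  id_of[fg] <- seq_along(fg)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1L, ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2L, c(offs$dz[k], offs$dy[k], offs$dx[k]), "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
    nid <- integer(nrow(nb))
    nid[ok] <- id_of[nb[ok, , drop = FALSE]]
    has <- ok & nid > 0L
    if (any(has)) edges <- rbind(edges, cbind(which(has), nid[has]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  out <- array(0L, dm)
  out[fg] <- as.integer(memb)
  out
}

# direct (gather-free) 3D cross-correlation with zero padding at one
# output position, for one output channel.
# X: l^3 x C_in (z fastest); W: (k^3 * C_in) x C_out with rows ordered
# input-channel-major, offsets z fastest within a channel
oracle_conv_at <- function(X, W, b, pos, l, k, c_out) {
  r <- (k - 1L) %/% 2L
  acc <- b[c_out]
  row <- 0L
  for (ci in seq_len(ncol(X))) {
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      row <- row + 1L
      p <- pos + c(dz, dy, dx)
      if (all(p >= 1L) && all(p <= l)) {
        flat <- (p[3L] - 1L) * l^2L + (p[2L] - 1L) * l + p[1L]
        acc <- acc + X[flat, ci] * W[row, c_out]
      }
    }
  }
  acc
}

# adaptive pooling cell range along one axis: bin j of k over m cells
# (floor/ceiling convention of classic spatial pyramid pooling)
oracle_bin_range <- function(m, k, j) {
  (floor((j - 1L) * m / k) + 1L):ceiling(j * m / k)
}

# exhaustive classification of every interior voxel at one radius,
# restricted to the connected component of the seeds: the reference for
# pruning correctness
oracle_decision_set <- function(vol_dim, classifier, r, theta, seeds,
                                connectivity = 26L) {
  dm <- vol_dim
  dec <- array(0L, dm)
  zi <- (r + 1L):(dm[1L] - r); yi <- (r + 1L):(dm[2L] - r); xi <- (r + 1L):(dm[3L] - r)
  centers <- as.matrix(expand.grid(z = zi, y = yi, x = xi))
  for (start in seq(1L, nrow(centers), by = 8192L)) {
    idx <- start:min(nrow(centers), start + 8191L)
    p <- classifier(centers[idx, , drop = FALSE], r)
    hit <- centers[idx[p >= theta], , drop = FALSE]
    dec[hit] <- 1L
  }
  oracle_flood_fill(dec, seeds, connectivity)
}
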