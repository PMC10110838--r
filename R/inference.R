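## Dynamic flood-filling inference with a locally adaptive field of view:
## growing (enqueue unseen neighbors of root voxels at the same radius),
## FoV reduction (re-enqueue a non-root voxel at the next smaller ladder
## radius), and pruning (re-evaluate, at the smallest radius, root voxels
## adjacent to a confidently non-root voxel, possibly retracting the
## boundary). Plus the naive voxel-wise baseline and connected-component
## filtering.

#' Inference configuration
#'
#' @param seeds 1-based `(z, y, x)` seed coordinate matrix (or vector for a
#'   single seed). For [weak_loop()] with several volumes, a named list of
#'   matrices.
#' @param fov_ladder strictly decreasing field-of-view radii; evaluation
#'   starts at the largest and falls back along the ladder. The default
#'   `c(7, 3, 2, 1)` starts at the largest training radius and ends at the
#'   smallest admissible FoV (edge 3).
#' @param theta root-probability threshold in (0, 1); a voxel is root when
#'   `p_root >= theta`. 0.5 and 0.2 are the named operating points.
#' @param connectivity neighborhood for growing/pruning, 26 (default; thin
#'   diagonal laterals stay connected) or 6.
#' @param mask optional [binary_volume()]; only voxels whose whole FoV lies
#'   inside the mask are evaluable, others count as non-root at that
#'   radius.
#' @param max_batch queue entries pulled and classified per step.
#' @return An `infer_config` list.
#' @export
infer_config <- function(seeds, fov_ladder = c(7L, 3L, 2L, 1L), theta = 0.5,
                         connectivity = 26L, mask = NULL, max_batch = 1024L) {
  fov_ladder <- as.integer(fov_ladder)
  if (length(fov_ladder) < 1L || any(diff(fov_ladder) >= 0L))
    stop("`fov_ladder` must be strictly decreasing")
  if (min(fov_ladder) < 1L) stop("minimum ladder radius must be >= 1")
  if (theta <= 0 || theta >= 1) stop("`theta` must be in (0, 1)")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (!is.null(mask)) stopifnot(inherits(mask, "binary_volume"))
  if (is.matrix(seeds) || is.numeric(seeds)) seeds <- rbind(seeds)
  structure(list(seeds = seeds, fov_ladder = fov_ladder, theta = theta,
                 connectivity = as.integer(connectivity), mask = mask,
                 max_batch = as.integer(max_batch)),
            class = "infer_config")
}

## growable FIFO queue of (voxel flat index, radius)
make_queue <- function(capacity = 4096L) {
  env <- new.env(parent = emptyenv())
  env$v <- integer(capacity); env$r <- integer(capacity)
  env$head <- 1L; env$tail <- 0L
  env
}

queue_push <- function(q, v, r) {
  n <- length(v)
  if (n == 0L) return(invisible(NULL))
  need <- q$tail + n
  if (need > length(q$v)) {
    newcap <- max(2L * length(q$v), need)
    q$v <- c(q$v, integer(newcap - length(q$v)))
    q$r <- c(q$r, integer(newcap - length(q$r)))
  }
  q$v[(q$tail + 1L):need] <- v
  q$r[(q$tail + 1L):need] <- r
  q$tail <- need
  invisible(NULL)
}

queue_pop <- function(q, n) {
  if (q$head > q$tail) return(NULL)
  last <- min(q$tail, q$head + n - 1L)
  out <- list(v = q$v[q$head:last], r = q$r[q$head:last])
  q$head <- last + 1L
  out
}

## voxels whose whole FoV at each ladder radius lies inside volume & mask
fov_valid_lookup <- function(dm, mask, ladder) {
  lookup <- list()
  for (r in ladder) {
    ok <- array(FALSE, dm)
    if (all(dm >= 2L * r + 1L)) {
      zi <- (r + 1L):(dm[1L] - r); yi <- (r + 1L):(dm[2L] - r); xi <- (r + 1L):(dm[3L] - r)
      if (is.null(mask)) {
        ok[zi, yi, xi] <- TRUE
      } else {
        bs <- box_sum(mask$data, r)
        full <- (2L * r + 1L)^3L
        ok[zi, yi, xi] <- bs[zi, yi, xi] == full
      }
    }
    lookup[[as.character(r)]] <- ok
  }
  lookup
}

#' Dynamic flood-filling inference
#'
#' Segments the root system connected to the seeds by flood-filling with a
#' locally adaptive field of view. Seeds enter the queue at the largest
#' ladder radius. Queue entries are popped in batches of at most
#' `max_batch` (duplicates collapse to their smallest radius) and
#' classified against the state snapshot at pop time; decisions are applied
#' after the whole batch, which makes the final segmentation independent of
#' the batch size for a deterministic classifier:
#'
#' * `p_root >= theta`: the voxel becomes root (recording the deciding
#'   radius) and all its unseen neighbors are enqueued at the same radius
#'   (growing). A root voxel re-evaluated at the smallest radius during
#'   pruning that is confirmed enqueues nothing.
#' * `p_root < theta` above the smallest radius: the voxel is re-enqueued
#'   at the next smaller ladder radius (FoV reduction).
#' * `p_root < theta` at the smallest radius: the voxel is finally
#'   non-root, and every neighboring root voxel that was decided at a
#'   larger radius is enqueued for re-evaluation at the smallest radius
#'   (pruning). A pruned voxel never re-grows: decisions at the smallest
#'   radius are final.
#'
#' A voxel whose FoV would leave the volume (or mask) counts as non-root at
#' that radius, triggering reduction. Each voxel is evaluated at most once
#' per ladder radius, which bounds the work and guarantees termination.
#'
#' @param vol the [gray_volume()] to segment.
#' @param classifier a function `(centers, r) -> p_root` (see
#'   [network_classifier()] and [make_oracle()]).
#' @param cfg an [infer_config()].
#' @return A `segmentation`: list with `roots` ([binary_volume()]),
#'   `provenance` (integer array; the deciding radius per root voxel, 0
#'   elsewhere), and `evaluations` (classifier decisions made).
#' @export
dynamic_infer <- function(vol, classifier, cfg) {
  stopifnot(inherits(cfg, "infer_config"))
  dm <- dim(vol_data(vol))
  seeds <- rbind(cfg$seeds)
  if (is.null(seeds) || nrow(seeds) == 0L) stop("seed list must not be empty")
  if (any(seeds < 1L) || any(sweep(seeds, 2L, dm, ">") ))
    stop("seeds must lie inside the volume")
  ladder <- cfg$fov_ladder
  r_min <- ladder[length(ladder)]
  next_radius <- stats::setNames(c(ladder[-1L], NA), as.character(ladder))
  offs <- neighbor_offsets(cfg$connectivity)
  valid <- fov_valid_lookup(dm, cfg$mask, ladder)
  if (!is.null(cfg$mask)) {
    inmask <- cfg$mask$data == 1L
    if (any(!inmask[seeds])) stop("seeds must lie inside the mask")
  } else inmask <- NULL

  n <- prod(dm)
  UNSEEN <- 0L; ROOT <- 2L; NONROOT <- 3L
  status <- integer(n)
  root_r <- integer(n)          # provenance: deciding radius of root voxels
  eval_floor <- rep(999L, n)    # smallest radius this voxel was evaluated at
  pending <- rep(999L, n)       # smallest radius currently queued

  q <- make_queue()
  push <- function(v, r) {
    keep <- pending[v] > r & eval_floor[v] > r
    v <- v[keep]
    if (length(v)) {
      pending[v] <<- r
      queue_push(q, v, r)
    }
  }

  neighbors_of <- function(v) {
    zyx <- flat_to_zyx(v, dm)
    res <- integer(0)
    for (i in seq_len(nrow(offs))) {
      nb <- sweep(zyx, 2L, offs[i, ], "+")
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
      res <- c(res, zyx_to_flat(nb[ok, , drop = FALSE], dm))
    }
    if (!is.null(inmask)) res <- res[inmask[res]]
    res
  }

  seed_idx <- zyx_to_flat(seeds, dm)
  push(unique(seed_idx), ladder[1L])
  evaluations <- 0L

  while (!is.null(batch <- queue_pop(q, cfg$max_batch))) {
    ## drop stale entries; collapse duplicates to the smallest radius
    keep <- pending[batch$v] == batch$r & eval_floor[batch$v] > batch$r
    v <- batch$v[keep]; r <- batch$r[keep]
    if (length(v) == 0L) next
    dup <- duplicated(v)
    v <- v[!dup]; r <- r[!dup]

    ## classify the whole batch against the state snapshot
    p <- numeric(length(v))
    for (rr in unique(r)) {
      sel <- which(r == rr)
      ok <- valid[[as.character(rr)]][v[sel]]
      p[sel[!ok]] <- -Inf                        # FoV leaves volume/mask
      if (any(ok)) {
        ctr <- flat_to_zyx(v[sel[ok]], dm)
        p[sel[ok]] <- classifier(ctr, rr)
        evaluations <- evaluations + sum(ok)
      }
    }

    ## apply all decisions, then enqueue
    eval_floor[v] <- pmin(eval_floor[v], r)
    pending[v] <- 999L
    is_root <- p >= cfg$theta
    confirmed <- is_root & status[v] == ROOT       # pruning re-evaluations
    status[v[is_root]] <- ROOT
    root_r[v[is_root]] <- r[is_root]
    reduce <- !is_root & r > r_min
    final_nonroot <- !is_root & r == r_min
    status[v[final_nonroot]] <- NONROOT
    root_r[v[final_nonroot]] <- 0L

    grow <- is_root & !confirmed
    if (any(grow)) for (rr in unique(r[grow])) {
      nb <- unique(neighbors_of(v[grow & r == rr]))
      push(nb[status[nb] == UNSEEN], rr)
    }
    if (any(reduce)) for (rr in unique(r[reduce])) {
      push(v[reduce & r == rr], next_radius[[as.character(rr)]])
    }
    if (any(final_nonroot)) {
      nb <- unique(neighbors_of(v[final_nonroot]))
      push(nb[status[nb] == ROOT & root_r[nb] > r_min], r_min)
    }
  }

  roots <- array(as.integer(status == ROOT), dm)
  if (sum(roots) == 0L)
    warning("all seeds classified non-root at all radii; segmentation is empty")
  prov <- array(root_r, dm)
  structure(list(roots = binary_volume(roots), provenance = prov,
                 evaluations = evaluations, config = cfg),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d root voxels, %d classifier evaluations\n",
              sum(x$roots$data), x$evaluations))
  if (sum(x$roots$data) > 0L) {
    tab <- table(x$provenance[x$provenance > 0L])
    cat("  deciding FoV radii:", paste(sprintf("r=%s: %d", names(tab), tab),
                                       collapse = ", "), "\n")
  }
  invisible(x)
}

#' Naive voxel-wise inference
#'
#' Classifies every voxel independently at one fixed field-of-view radius:
#' a voxel is root when its probability reaches `theta` and its whole FoV
#' lies inside the volume (out-of-margin voxels are non-root). The result
#' typically contains clutter components away from the root system, which
#' [cca_filter()] removes.
#'
#' @param vol the [gray_volume()].
#' @param classifier `(centers, r) -> p_root`.
#' @param r field-of-view radius.
#' @param theta root-probability threshold.
#' @param mask optional [binary_volume()]; only voxels with `mask == 1` are
#'   evaluated.
#' @param chunk centers classified per call.
#' @return A [binary_volume()].
#' @export
naive_infer <- function(vol, classifier, r, theta = 0.5, mask = NULL,
                        chunk = 8192L) {
  dm <- dim(vol_data(vol))
  r <- as.integer(r)
  if (r < 1L) stop("`r` must be >= 1")
  out <- array(0L, dm)
  if (any(dm < 2L * r + 1L)) return(binary_volume(out))
  interior <- array(FALSE, dm)
  interior[(r + 1L):(dm[1L] - r), (r + 1L):(dm[2L] - r), (r + 1L):(dm[3L] - r)] <- TRUE
  if (!is.null(mask)) interior <- interior & mask$data == 1L
  centers <- which(interior)
  for (start in seq(1L, length(centers), by = chunk)) {
    idx <- centers[start:min(length(centers), start + chunk - 1L)]
    p <- classifier(flat_to_zyx(idx, dm), r)
    out[idx[p >= theta]] <- 1L
  }
  binary_volume(out)
}

#' Label connected components of a binary volume
#'
#' Breadth-first labeling under 6- or 26-connectivity.
#'
#' @param bin a [binary_volume()].
#' @param connectivity 6 or 26.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(bin, connectivity = 26L) {
  stopifnot(inherits(bin, "binary_volume"))
  dm <- dim(bin$data)
  offs <- neighbor_offsets(as.integer(connectivity))
  labels <- array(0L, dm)
  fg <- bin$data == 1L
  todo <- which(fg)
  cur <- 0L
  visited <- !fg
  for (s in todo) {
    if (visited[s]) next
    cur <- cur + 1L
    frontier <- s
    visited[s] <- TRUE
    labels[s] <- cur
    while (length(frontier)) {
      zyx <- flat_to_zyx(frontier, dm)
      nxt <- integer(0)
      for (i in seq_len(nrow(offs))) {
        nb <- sweep(zyx, 2L, offs[i, ], "+")
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
              nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
              nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
        cand <- zyx_to_flat(nb[ok, , drop = FALSE], dm)
        nxt <- c(nxt, cand[!visited[cand]])
      }
      nxt <- unique(nxt)
      nxt <- nxt[!visited[nxt]]
      visited[nxt] <- TRUE
      labels[nxt] <- cur
      frontier <- nxt
    }
  }
  labels
}

#' Remove small connected components
#'
#' Connected-component filtering of a naive segmentation: every component
#' with fewer than `min_size` voxels is deleted; components reaching
#' `min_size` are kept unchanged.
#'
#' @param bin a [binary_volume()].
#' @param min_size minimal component voxel count to keep (default 1000).
#' @param connectivity 6 or 26.
#' @return A filtered [binary_volume()].
#' @export
cca_filter <- function(bin, min_size = 1000L, connectivity = 26L) {
  if (min_size < 1L) stop("`min_size` must be >= 1")
  if (min_size == 1L) return(bin)
  labels <- label_components(bin, connectivity)
  if (max(labels) == 0L) return(bin)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_size)
  binary_volume(array(as.integer(labels %in% keep & labels > 0L), dim(labels)))
}

#' Propose a seed voxel from a bright top slab
#'
#' Utility for initializing the flood fill: returns the brightest voxel in
#' a user-given slab of top slices, where the plant stem dominates the
#' gray values.
#'
#' @param vol a [gray_volume()].
#' @param z_range slice range (1-based, inclusive) to search.
#' @return A 1-row `(z, y, x)` matrix.
#' @export
propose_seed <- function(vol, z_range) {
  stopifnot(inherits(vol, "gray_volume"))
  dm <- dim(vol$data)
  z_range <- max(1L, z_range[1L]):min(dm[1L], z_range[length(z_range)])
  slab <- vol$data[z_range, , , drop = FALSE]
  best <- which.max(slab)
  zyx <- flat_to_zyx(best, dim(slab))
  zyx[, 1L] <- zyx[, 1L] + z_range[1L] - 1L
  zyx
}
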