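#' Configuration for a synthetic root phantom
#'
#' Describes the scene the segmentation method assumes: a potted plant with
#' a bright vertical stem, a branching tree of root tubes whose radii span
#' storage-root scale (several voxels) down to lateral-root scale (about
#' one voxel), inhomogeneous soil containing pebble distractors whose gray
#' level is confusable with roots, a pot wall and bottom, and air above the
#' soil line.
#'
#' Gray levels are free parameters of the phantom; the defaults put soil at
#' 100 +/- 15, roots at 160 and pebbles at 165 on an arbitrary 8-bit-like
#' scale, so pebbles sit within one soil standard deviation of the root
#' mean and act as hard negatives for a brightness-only classifier.
#'
#' @param shape volume dimensions `(nz, ny, nx)` in voxels.
#' @param spacing_um voxel edge length in micrometers.
#' @param stem_radius_vox radius of the vertical stem tube.
#' @param branch_levels number of branching generations (0 = stem only).
#' @param radius_range_vox `(max, min)` root tube radius; level-1 branches
#'   use the max, terminal branches the min (>= 1 voxel).
#' @param n_branches_per_level branches sprouting from each parent.
#' @param soil_gray_mean,soil_gray_sd soil gray level and noise sd (the sd
#'   is also used as the global additive noise level).
#' @param root_gray_mean root gray level; must exceed `soil_gray_mean`.
#' @param pebble_count,pebble_radius_vox,pebble_gray_mean spherical soil
#'   distractors; `pebble_gray_mean` must lie within one `soil_gray_sd`
#'   of `root_gray_mean` so pebbles are genuinely root-like.
#' @param pot_wall_thickness_vox thickness of pot wall and bottom plate.
#' @param air_fraction fraction of the z extent that is air above the soil.
#' @param pot_gray_mean,air_gray_mean gray levels of pot and air.
#' @param seed integer seed; all phantom randomness flows from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(96L, 96L, 96L), spacing_um = 175,
                           stem_radius_vox = 4, branch_levels = 3L,
                           radius_range_vox = c(5, 1),
                           n_branches_per_level = 2L,
                           soil_gray_mean = 100, soil_gray_sd = 15,
                           root_gray_mean = 160,
                           pebble_count = 6L, pebble_radius_vox = 3,
                           pebble_gray_mean = 165,
                           pot_wall_thickness_vox = 3L,
                           air_fraction = 0.15,
                           pot_gray_mean = 55, air_gray_mean = 5,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("`shape` must be 3 positive integers")
  if (radius_range_vox[2L] < 1) stop("minimum root radius must be >= 1 voxel")
  if (radius_range_vox[1L] < radius_range_vox[2L])
    stop("`radius_range_vox` must be (max, min)")
  if (root_gray_mean <= soil_gray_mean)
    stop("roots must be brighter than soil (root_gray_mean > soil_gray_mean)")
  if (abs(pebble_gray_mean - root_gray_mean) > soil_gray_sd)
    stop("pebble_gray_mean must lie within one soil_gray_sd of root_gray_mean")
  if (air_fraction < 0 || air_fraction >= 1) stop("`air_fraction` must be in [0, 1)")
  structure(list(shape = shape, spacing_um = spacing_um,
                 stem_radius_vox = stem_radius_vox,
                 branch_levels = as.integer(branch_levels),
                 radius_range_vox = as.numeric(radius_range_vox),
                 n_branches_per_level = as.integer(n_branches_per_level),
                 soil_gray_mean = soil_gray_mean, soil_gray_sd = soil_gray_sd,
                 root_gray_mean = root_gray_mean,
                 pebble_count = as.integer(pebble_count),
                 pebble_radius_vox = pebble_radius_vox,
                 pebble_gray_mean = pebble_gray_mean,
                 pot_wall_thickness_vox = as.integer(pot_wall_thickness_vox),
                 air_fraction = air_fraction,
                 pot_gray_mean = pot_gray_mean, air_gray_mean = air_gray_mean,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

## voxels (integer centers) within `radius` of the segment p0-p1, as flat
## indices; tubes are defined in continuous coordinates and rasterized, so
## branches stay smooth down to radius-1 laterals
raster_tube <- function(dm, p0, p1, radius) {
  lo <- pmax(1L, floor(pmin(p0, p1) - radius))
  hi <- pmin(dm, ceiling(pmax(p0, p1) + radius))
  if (any(lo > hi)) return(integer(0))
  g <- expand.grid(z = lo[1L]:hi[1L], y = lo[2L]:hi[2L], x = lo[3L]:hi[3L])
  P <- as.matrix(g)
  v <- p1 - p0
  vv <- sum(v * v)
  W <- sweep(P, 2L, p0)
  t <- if (vv > 0) pmin(1, pmax(0, as.vector(W %*% v) / vv)) else rep(0, nrow(P))
  D <- W - outer(t, v)
  inside <- rowSums(D * D) <= radius^2
  zyx_to_flat(P[inside, , drop = FALSE], dm)
}

#' Generate a synthetic root phantom
#'
#' Builds the gray volume and the ground-truth root / sediment / pot / air
#' masks for a [phantom_config()]. The four masks are pairwise disjoint and
#' partition the volume; the root system is a recursive tube tree rooted in
#' the stem and is one 26-connected component containing every seed. The
#' result is bitwise reproducible for a given config.
#'
#' @param cfg a [phantom_config()].
#' @return A `phantom` list with elements `gray` ([gray_volume()]), `roots`,
#'   `sediment`, `pot`, `air` ([binary_volume()]s), `seeds` (matrix of
#'   1-based `(z, y, x)` stem voxels), `branch_index` (integer array of
#'   per-voxel branch ids, 0 outside roots, with a `branches` attribute
#'   holding the branch table: id, parent, level, radius, terminal), and
#'   `soil_line_z` (last air slice index).
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  dm <- cfg$shape
  nz <- dm[1L]; ny <- dm[2L]; nx <- dm[3L]
  thick <- cfg$pot_wall_thickness_vox
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  rpot <- min(ny, nx) / 2 - thick - 1
  z_soil <- max(1L, round(cfg$air_fraction * nz))
  z_bottom <- nz - thick                      # last sediment slice
  if (rpot < cfg$stem_radius_vox + 3 || z_bottom - z_soil < 8)
    stop("`shape` too small to host the stem and pot geometry")

  with_seed(cfg$seed, {
    ## --- root tube tree in continuous (z, y, x) coordinates ---
    z_start <- max(2, z_soil - max(2, round(0.05 * nz)))
    z_stem_end <- z_soil + round(0.55 * (z_bottom - z_soil))
    segs <- list(list(id = 1L, parent = 0L, level = 0L,
                      radius = cfg$stem_radius_vox,
                      p0 = c(z_start, cy, cx), p1 = c(z_stem_end, cy, cx)))
    if (cfg$branch_levels > 0L) {
      radii <- if (cfg$branch_levels == 1L) cfg$radius_range_vox[1L] else
        seq(cfg$radius_range_vox[1L], cfg$radius_range_vox[2L],
            length.out = cfg$branch_levels)
      parents <- list(segs[[1L]])
      next_id <- 2L
      for (lev in seq_len(cfg$branch_levels)) {
        children <- list()
        for (par in parents) {
          for (k in seq_len(cfg$n_branches_per_level)) {
            tfrac <- if (par$level == 0L) runif(1, 0.35, 0.95) else runif(1, 0.2, 0.95)
            att <- par$p0 + tfrac * (par$p1 - par$p0)
            att[1L] <- max(att[1L], z_soil + 2)      # branches start below soil
            dz <- runif(1, 0.1, 0.8)
            phi <- runif(1, 0, 2 * pi)
            h <- sqrt(1 - dz^2)
            u <- c(dz, h * sin(phi), h * cos(phi))
            len <- runif(1, 0.35, 0.6) * rpot / sqrt(lev)
            rad <- radii[lev]
            q <- att + len * u
            ## shrink until the endpoint stays inside the soil region
            for (it in 1:30) {
              rr <- sqrt((q[2L] - cy)^2 + (q[3L] - cx)^2)
              if (rr <= rpot - 1 - rad && q[1L] <= z_bottom - 1 - rad &&
                  q[1L] >= z_soil + 1 + rad) break
              len <- 0.7 * len
              q <- att + len * u
            }
            children[[length(children) + 1L]] <-
              list(id = next_id, parent = par$id, level = lev, radius = rad,
                   p0 = att, p1 = q)
            next_id <- next_id + 1L
          }
        }
        segs <- c(segs, children)
        parents <- children
      }
    }

    ## rasterize; first-claiming segment owns each voxel
    branch_index <- array(0L, dm)
    for (s in segs) {
      idx <- raster_tube(dm, s$p0, s$p1, s$radius)
      idx <- idx[branch_index[idx] == 0L]
      branch_index[idx] <- s$id
    }
    roots <- array(as.integer(branch_index > 0L), dm)

    ## --- scene masks (priority: roots > air > pot > sediment) ---
    zc <- slice.index(roots, 1L)
    rad2 <- (slice.index(roots, 2L) - cy)^2 + (slice.index(roots, 3L) - cx)^2
    in_pot_interior <- rad2 <= rpot^2
    wall <- rad2 > rpot^2 & rad2 <= (rpot + thick)^2 & zc >= max(1L, z_soil - 2L)
    bottom <- zc > z_bottom & rad2 <= (rpot + thick)^2
    pot_region <- wall | bottom
    sediment_region <- in_pot_interior & zc > z_soil & zc <= z_bottom
    air_region <- !pot_region & !sediment_region

    ## --- pebbles: root-like spheres in the sediment ---
    pebbles <- array(FALSE, dm)
    pr <- cfg$pebble_radius_vox
    placed <- 0L
    tries <- 0L
    while (placed < cfg$pebble_count && tries < 100L * max(1L, cfg$pebble_count)) {
      tries <- tries + 1L
      pz <- runif(1, z_soil + pr + 2, z_bottom - pr - 1)
      ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * (rpot - pr - 2)
      py <- cy + rr * sin(ang); px <- cx + rr * cos(ang)
      lo <- pmax(1L, floor(c(pz, py, px) - pr - 1))
      hi <- pmin(dm, ceiling(c(pz, py, px) + pr + 1))
      if (any(roots[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] > 0L)) next
      idx <- raster_tube(dm, c(pz, py, px), c(pz, py, px), pr)
      pebbles[idx] <- TRUE
      placed <- placed + 1L
    }

    ## --- gray values: class means + Gaussian noise ---
    gray <- array(cfg$soil_gray_mean, dm)
    gray[air_region] <- cfg$air_gray_mean
    gray[pot_region] <- cfg$pot_gray_mean
    gray[pebbles] <- cfg$pebble_gray_mean
    gray[roots > 0L] <- cfg$root_gray_mean
    gray <- gray + rnorm(length(gray), 0, cfg$soil_gray_sd)

    ## --- seeds on the stem axis just below the soil line ---
    sz <- unique(pmin(z_soil + c(2L, 5L, 8L), z_stem_end))
    seeds <- cbind(z = sz, y = rep(round(cy), length(sz)), x = rep(round(cx), length(sz)))
    seeds <- seeds[roots[cbind(seeds[, 1L], seeds[, 2L], seeds[, 3L])] == 1L, , drop = FALSE]

    branches <- do.call(rbind, lapply(segs, function(s)
      data.frame(id = s$id, parent = s$parent, level = s$level, radius = s$radius)))
    child_of <- unique(branches$parent)
    branches$terminal <- !(branches$id %in% child_of)
    attr(branch_index, "branches") <- branches

    root_mask <- roots > 0L
    structure(list(
      gray = gray_volume(gray, cfg$spacing_um),
      roots = binary_volume(roots),
      sediment = binary_volume(array(as.integer(sediment_region & !root_mask), dm)),
      pot = binary_volume(array(as.integer(pot_region & !root_mask), dm)),
      air = binary_volume(array(as.integer(air_region & !root_mask), dm)),
      seeds = seeds,
      branch_index = branch_index,
      soil_line_z = z_soil,
      config = cfg), class = "phantom")
  })
}

#' Configuration for weak-label corruption
#'
#' Describes how an analytical pre-segmentation typically degrades a true
#' root mask: fine lateral roots are missed entirely, tube surfaces are
#' systematically over- or under-segmented by about one voxel, and
#' root-like soil structures are picked up as false positives. Applying
#' this corruption to phantom ground truth yields the initial weak label
#' volume for the weakly supervised loop.
#'
#' @param thin_root_drop_prob probability of deleting each terminal branch
#'   whose radius is at most `thin_radius_cutoff`.
#' @param surface_dilate_prob,surface_erode_prob per-branch probabilities
#'   of a 1-voxel morphological dilation / erosion of the branch surface.
#' @param blob_fp_count,blob_fp_radius_vox false-positive spherical blobs
#'   added off-root.
#' @param thin_radius_cutoff radius (voxels) below which a terminal branch
#'   counts as thin; default 1.5, i.e. roughly one-voxel laterals.
#' @param seed integer seed.
#' @return A `label_noise_config` list.
#' @export
label_noise_config <- function(thin_root_drop_prob = 0.5,
                               surface_dilate_prob = 0.25,
                               surface_erode_prob = 0.25,
                               blob_fp_count = 4L, blob_fp_radius_vox = 3,
                               thin_radius_cutoff = 1.5, seed = 1L) {
  for (p in c(thin_root_drop_prob, surface_dilate_prob, surface_erode_prob))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  structure(list(thin_root_drop_prob = thin_root_drop_prob,
                 surface_dilate_prob = surface_dilate_prob,
                 surface_erode_prob = surface_erode_prob,
                 blob_fp_count = as.integer(blob_fp_count),
                 blob_fp_radius_vox = blob_fp_radius_vox,
                 thin_radius_cutoff = thin_radius_cutoff,
                 seed = as.integer(seed)),
            class = "label_noise_config")
}

## 6-neighbor flat offsets that stay in bounds, as an index matrix
adjacent6 <- function(idx, dm) {
  zyx <- flat_to_zyx(idx, dm)
  offs <- neighbor_offsets(6L)
  out <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(zyx, 2L, offs[i, ], "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
    out[[i]] <- zyx_to_flat(nb[ok, , drop = FALSE], dm)
  }
  unlist(out)
}

#' Corrupt a root label volume into weak labels
#'
#' Emulates the defects of an analytical reference segmentation used as
#' initial training labels. Pseudo-random draws are consumed in a fixed
#' documented order (one uniform per eligible thin terminal branch in
#' increasing id order, then one uniform per non-stem branch for the
#' surface operation, then the blob placements), so runs replay exactly
#' for a given seed.
#'
#' @param roots ground-truth [binary_volume()].
#' @param branch_index integer array of per-voxel branch ids aligned with
#'   `roots`, carrying a `branches` attribute (as produced by
#'   [generate_phantom()]).
#' @param cfg a [label_noise_config()].
#' @param sediment optional [binary_volume()]; when given, false-positive
#'   blobs are centered on sediment voxels only.
#' @return A [binary_volume()] of corrupted labels.
#' @export
corrupt_labels <- function(roots, branch_index, cfg, sediment = NULL) {
  stopifnot(inherits(roots, "binary_volume"), inherits(cfg, "label_noise_config"))
  dm <- dim(roots$data)
  if (!identical(dim(branch_index), dm)) stop("`branch_index` must align with `roots`")
  branches <- attr(branch_index, "branches")
  if (is.null(branches)) stop("`branch_index` lacks its `branches` attribute")
  out <- roots$data
  with_seed(cfg$seed, {
    ## 1) drop thin terminal branches (stem, id 1, is never dropped)
    thin <- branches[branches$terminal & branches$radius <= cfg$thin_radius_cutoff &
                     branches$id != 1L, , drop = FALSE]
    thin <- thin[order(thin$id), , drop = FALSE]
    dropped <- integer(0)
    for (id in thin$id) {
      if (runif(1) < cfg$thin_root_drop_prob) dropped <- c(dropped, id)
    }
    for (id in dropped) out[branch_index == id] <- 0L
    ## 2) per-branch 1-voxel surface dilation / erosion
    others <- setdiff(branches$id[branches$id != 1L], dropped)
    for (id in sort(others)) {
      u <- runif(1)
      vox <- which(branch_index == id)
      if (length(vox) == 0L) next
      if (u < cfg$surface_dilate_prob) {
        nb <- unique(adjacent6(vox, dm))
        out[nb[out[nb] == 0L]] <- 1L
      } else if (u < cfg$surface_dilate_prob + cfg$surface_erode_prob) {
        ## surface voxels: those with a 6-neighbor outside the true root set
        zyx <- flat_to_zyx(vox, dm)
        offs <- neighbor_offsets(6L)
        surface <- rep(FALSE, length(vox))
        for (i in seq_len(nrow(offs))) {
          nb <- sweep(zyx, 2L, offs[i, ], "+")
          ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
                nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
                nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
          outside <- rep(TRUE, length(vox))
          outside[ok] <- roots$data[zyx_to_flat(nb[ok, , drop = FALSE], dm)] == 0L
          surface <- surface | outside
        }
        out[vox[surface]] <- 0L
      }
    }
    ## 3) false-positive blobs off-root
    sed_idx <- if (!is.null(sediment)) which(sediment$data == 1L) else NULL
    placed <- 0L; tries <- 0L
    br <- cfg$blob_fp_radius_vox
    while (placed < cfg$blob_fp_count && tries < 100L * max(1L, cfg$blob_fp_count)) {
      tries <- tries + 1L
      ctr <- if (!is.null(sed_idx)) {
        as.numeric(flat_to_zyx(sed_idx[sample.int(length(sed_idx), 1L)], dm))
      } else {
        c(runif(1, br + 1, dm[1L] - br), runif(1, br + 1, dm[2L] - br),
          runif(1, br + 1, dm[3L] - br))
      }
      lo <- pmax(1L, floor(ctr - br - 1)); hi <- pmin(dm, ceiling(ctr + br + 1))
      if (any(roots$data[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] > 0L)) next
      out[raster_tube(dm, ctr, ctr, br)] <- 1L
      placed <- placed + 1L
    }
  })
  binary_volume(out)
}

#' Configuration for the ground-truth classifier oracle
#'
#' @param blur_weight mixing weight `w` in `[0, 1]` between the center
#'   voxel's true class (`w = 0`: a perfect, FoV-independent classifier)
#'   and the mean true-root content of the whole field of view (`w = 1`:
#'   a classifier whose prediction is entirely skewed by off-center roots,
#'   the failure mode that large fields of view exhibit near boundaries).
#' @return An `oracle_config` list.
#' @export
oracle_config <- function(blur_weight = 0) {
  if (blur_weight < 0 || blur_weight > 1) stop("`blur_weight` must be in [0, 1]")
  structure(list(blur_weight = blur_weight), class = "oracle_config")
}

## 3D summed-area table padded with zeros at index 0
integral_image <- function(arr) {
  dm <- dim(arr)
  cs <- arr
  storage.mode(cs) <- "double"
  cs <- apply(cs, c(2L, 3L), cumsum)
  cs <- aperm(apply(cs, c(1L, 3L), cumsum), c(2L, 1L, 3L))
  cs <- aperm(apply(cs, c(1L, 2L), cumsum), c(2L, 3L, 1L))
  pad <- array(0, dm + 1L)
  pad[-1L, -1L, -1L] <- cs
  pad
}

## cube sums at given centers (k x 3 zyx matrix) from a padded integral
box_sum_at <- function(pad, centers, r) {
  centers <- rbind(centers)
  P <- function(z, y, x) pad[cbind(z, y, x)]
  z <- centers[, 1L]; y <- centers[, 2L]; x <- centers[, 3L]
  hz <- z + r + 1L; hy <- y + r + 1L; hx <- x + r + 1L
  lz <- z - r; ly <- y - r; lx <- x - r
  P(hz, hy, hx) - P(lz, hy, hx) - P(hz, ly, hx) - P(hz, hy, lx) +
    P(lz, ly, hx) + P(lz, hy, lx) + P(hz, ly, lx) - P(lz, ly, lx)
}

#' Build a ground-truth classifier oracle
#'
#' Returns a classifier with the same calling contract as a trained network
#' classifier: `function(centers, r)` mapping a matrix of 1-based
#' `(z, y, x)` centers and a field-of-view radius to root probabilities.
#' The probability is `(1 - w) * truth(center) + w * mean(truth over FoV)`,
#' so `w = 0` is a perfect center-voxel oracle at every FoV size while
#' larger `w` reproduces the boundary blur of context-dominated
#' classifiers. A FoV extending outside the volume violates the caller
#' contract and raises an error.
#'
#' @param roots ground-truth [binary_volume()].
#' @param cfg an [oracle_config()].
#' @return A function `(centers, r) -> numeric vector of p_root`.
#' @export
make_oracle <- function(roots, cfg = oracle_config()) {
  stopifnot(inherits(roots, "binary_volume"), inherits(cfg, "oracle_config"))
  dm <- dim(roots$data)
  w <- cfg$blur_weight
  pad <- if (w > 0) integral_image(roots$data) else NULL
  dat <- roots$data
  function(centers, r) {
    centers <- rbind(centers)
    if (any(centers[, 1L] <= r | centers[, 1L] > dm[1L] - r |
            centers[, 2L] <= r | centers[, 2L] > dm[2L] - r |
            centers[, 3L] <= r | centers[, 3L] > dm[3L] - r))
      stop("field of view extends outside the volume")
    truth <- dat[centers]
    if (w == 0) return(as.numeric(truth))
    l3 <- (2 * r + 1)^3
    (1 - w) * truth + w * box_sum_at(pad, centers, r) / l3
  }
}
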