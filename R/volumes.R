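#' 3D gray-value volume with voxel spacing
#'
#' A `gray_volume` holds a 3D scalar field (for example a CT reconstruction
#' of a potted plant) together with its isotropic voxel edge length. The
#' array is indexed `[z, y, x]` with `z = 1` at the top of the volume (the
#' air side), so seed coordinates and masks share one fixed convention
#' throughout the package.
#'
#' @param data numeric 3D array, dimension `(nz, ny, nx)`; all values must
#'   be finite.
#' @param spacing_um isotropic voxel edge length in micrometers (> 0).
#' @return An object of class `gray_volume` with elements `data` and
#'   `spacing_um`.
#' @examples
#' v <- gray_volume(array(rnorm(8), c(2, 2, 2)), spacing_um = 175)
#' dim(v$data)
#' @export
gray_volume <- function(data, spacing_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (nz, ny, nx)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("`data` must be finite everywhere")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L ||
      !is.finite(spacing_um) || spacing_um <= 0)
    stop("`spacing_um` must be a single positive number")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing_um = as.numeric(spacing_um)),
            class = "gray_volume")
}

#' Binary mask volume
#'
#' A `binary_volume` holds a 3D mask of 0/1 values in the same `(nz, ny, nx)`
#' layout as [gray_volume()]. Masks are used for root / sediment / pot / air
#' labels and for restricting inference.
#'
#' @param data 3D array whose values are all 0 or 1 (logical arrays are
#'   accepted and converted).
#' @return An object of class `binary_volume` with element `data`
#'   (integer array of 0/1).
#' @examples
#' m <- binary_volume(array(0L, c(4, 4, 4)))
#' sum(m$data)
#' @export
binary_volume <- function(data) {
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (nz, ny, nx)")
  if (!all(data %in% c(0L, 1L)))
    stop("`data` values must all be 0 or 1")
  storage.mode(data) <- "integer"
  structure(list(data = data), class = "binary_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gray_volume> %d x %d x %d voxels (z,y,x), spacing %.4g um, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing_um, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_volume> %d x %d x %d voxels (z,y,x), %d foreground\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' @export
dim.gray_volume <- function(x) dim(x$data)

#' @export
dim.binary_volume <- function(x) dim(x$data)

vol_data <- function(x) {
  if (inherits(x, "gray_volume") || inherits(x, "binary_volume")) x$data else x
}

stopifnot_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop(sprintf("%s must share one shape (got %s vs %s)", what,
                 paste(dim(vol_data(a)), collapse = "x"),
                 paste(dim(vol_data(b)), collapse = "x")))
  invisible(TRUE)
}

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched, so all package randomness flows from explicit
## integer seeds.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## flat index <-> (z,y,x) helpers; z varies fastest (R column-major on
## arrays dimensioned (nz, ny, nx))
zyx_to_flat <- function(zyx, dm) {
  zyx <- rbind(zyx)
  (zyx[, 3L] - 1L) * (dm[1L] * dm[2L]) + (zyx[, 2L] - 1L) * dm[1L] + zyx[, 1L]
}

flat_to_zyx <- function(idx, dm) {
  idx0 <- idx - 1L
  z <- idx0 %% dm[1L]
  y <- (idx0 %/% dm[1L]) %% dm[2L]
  x <- idx0 %/% (dm[1L] * dm[2L])
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

## Cube-sum filter: S[v] = sum of `arr` over the cube of edge 2r+1 centered
## on v, computed with a 3D summed-area table. Voxels whose cube leaves the
## volume get NA.
box_sum <- function(arr, r) {
  dm <- dim(arr)
  if (any(dm < 2L * r + 1L)) stop("volume smaller than the box at this radius")
  cs <- arr
  storage.mode(cs) <- "double"
  ## cumulative sums along each axis
  cs <- apply(cs, c(2L, 3L), cumsum)                      # along z
  cs <- aperm(apply(cs, c(1L, 3L), cumsum), c(2L, 1L, 3L)) # along y
  cs <- aperm(apply(cs, c(1L, 2L), cumsum), c(2L, 3L, 1L)) # along x
  ## pad with zeros at index 0
  pad <- array(0, dm + 1L)
  pad[-1L, -1L, -1L] <- cs
  out <- array(NA_real_, dm)
  zi <- (r + 1L):(dm[1L] - r); yi <- (r + 1L):(dm[2L] - r); xi <- (r + 1L):(dm[3L] - r)
  hi <- function(i) i + r + 1L
  lo <- function(i) i - r
  out[zi, yi, xi] <-
    pad[hi(zi), hi(yi), hi(xi)] - pad[lo(zi), hi(yi), hi(xi)] -
    pad[hi(zi), lo(yi), hi(xi)] - pad[hi(zi), hi(yi), lo(xi)] +
    pad[lo(zi), lo(yi), hi(xi)] + pad[lo(zi), hi(yi), lo(xi)] +
    pad[hi(zi), lo(yi), lo(xi)] - pad[lo(zi), lo(yi), lo(xi)]
  out
}

## neighbor coordinate offsets for 6- or 26-connectivity
neighbor_offsets <- function(connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}
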