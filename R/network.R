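## The voxel classifier: five 3D convolution stages (spatial-preserving
## padding), a spatial pyramid pooling layer that turns a cubic feature map
## of any edge length into a fixed-length descriptor, and a three-layer
## fully connected head ending in a two-class softmax. Convolutions are
## evaluated as gather + matrix multiply so the heavy lifting runs in BLAS;
## the adaptive pooling runs in compiled code.

.rootfill_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.rootfill_cache[[key]])) .rootfill_cache[[key]] <- make()
  .rootfill_cache[[key]]
}

#' Network architecture configuration
#'
#' @param conv_channels five strictly increasing channel counts for the
#'   convolution stages. Defaults are deliberately small so that the
#'   network trains on a desktop CPU; widths are fully configurable.
#' @param kernel_edge odd convolution kernel edge in voxels (default 5,
#'   i.e. 5 x 5 x 5 kernels).
#' @param spp_levels increasing cubic output edges of the pyramid levels
#'   (default `c(1, 2, 4)`, a 73-bin descriptor per channel).
#' @param fc_sizes two hidden widths of the classification head; the output
#'   layer is always 2 classes.
#' @param dropout_conv,dropout_fc dropout probabilities applied after each
#'   convolution stage (default 0.40) and after each hidden fully connected
#'   layer (default 0.70); active only during training.
#' @param activation `"relu"` (the only supported rectifier).
#' @param pool pooling type inside the pyramid bins, `"max"` (default) or
#'   `"mean"`.
#' @param normalize whether pipeline helpers z-score each gray volume
#'   before patch extraction.
#' @return A `net_config` list.
#' @export
net_config <- function(conv_channels = c(8L, 16L, 32L, 64L, 128L),
                       kernel_edge = 5L, spp_levels = c(1L, 2L, 4L),
                       fc_sizes = c(256L, 64L),
                       dropout_conv = 0.40, dropout_fc = 0.70,
                       activation = "relu", pool = c("max", "mean"),
                       normalize = TRUE) {
  conv_channels <- as.integer(conv_channels)
  if (length(conv_channels) != 5L || any(diff(conv_channels) <= 0L))
    stop("`conv_channels` must be 5 strictly increasing counts")
  kernel_edge <- as.integer(kernel_edge)
  if (kernel_edge < 1L || kernel_edge %% 2L == 0L)
    stop("`kernel_edge` must be odd and >= 1")
  spp_levels <- as.integer(spp_levels)
  if (any(spp_levels < 1L) || any(diff(spp_levels) <= 0L))
    stop("`spp_levels` must be positive and increasing")
  fc_sizes <- as.integer(fc_sizes)
  if (length(fc_sizes) != 2L || any(fc_sizes < 1L))
    stop("`fc_sizes` must give 2 hidden widths")
  for (p in c(dropout_conv, dropout_fc))
    if (p < 0 || p >= 1) stop("dropout probabilities must be in [0, 1)")
  if (!identical(activation, "relu")) stop("only 'relu' activation is supported")
  pool <- match.arg(pool)
  structure(list(conv_channels = conv_channels, kernel_edge = kernel_edge,
                 spp_levels = spp_levels, fc_sizes = fc_sizes,
                 dropout_conv = dropout_conv, dropout_fc = dropout_fc,
                 activation = activation, pool = pool, normalize = normalize),
            class = "net_config")
}

#' Descriptor length per channel of a pyramid
#' @param spp_levels level edges.
#' @return `sum(spp_levels^3)` (73 for levels 1, 2, 4).
#' @export
spp_descriptor_bins <- function(spp_levels) as.integer(sum(as.integer(spp_levels)^3))

#' Build a randomly initialized network
#'
#' Weights use He initialization (`sd = sqrt(2 / fan_in)`); biases start at
#' zero. The parameter count is independent of the input edge length: the
#' convolutions preserve spatial extent (same-size padding) and the pyramid
#' pooling emits a fixed-length descriptor, so one network serves every
#' field-of-view size.
#'
#' @param cfg a [net_config()].
#' @param seed integer seed for the initialization.
#' @return An object of class `spp_net`.
#' @export
build_network <- function(cfg = net_config(), seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  k3 <- cfg$kernel_edge^3L
  chain <- c(1L, cfg$conv_channels)
  desc_len <- cfg$conv_channels[5L] * spp_descriptor_bins(cfg$spp_levels)
  fc_chain <- c(desc_len, cfg$fc_sizes, 2L)
  with_seed(seed, {
    conv <- lapply(seq_len(5L), function(i) {
      fan_in <- k3 * chain[i]
      list(W = matrix(rnorm(fan_in * chain[i + 1L], 0, sqrt(2 / fan_in)),
                      fan_in, chain[i + 1L]),
           b = numeric(chain[i + 1L]))
    })
    fc <- lapply(seq_len(3L), function(i) {
      fan_in <- fc_chain[i]
      list(W = matrix(rnorm(fan_in * fc_chain[i + 1L], 0, sqrt(2 / fan_in)),
                      fan_in, fc_chain[i + 1L]),
           b = numeric(fc_chain[i + 1L]))
    })
    structure(list(config = cfg, conv = conv, fc = fc, desc_len = desc_len),
              class = "spp_net")
  })
}

#' @export
print.spp_net <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(c(x$conv, x$fc), function(ly) length(ly$W) + length(ly$b), numeric(1)))
  cat("<spp_net>\n")
  cat(sprintf("  conv stages : 5 x (%d^3 kernels, same padding), channels 1 -> %s\n",
              cfg$kernel_edge, paste(cfg$conv_channels, collapse = " -> ")))
  cat(sprintf("  SPP levels  : %s (%d bins/channel, %s pooling) -> descriptor %d\n",
              paste(cfg$spp_levels, collapse = "/"),
              spp_descriptor_bins(cfg$spp_levels), cfg$pool, x$desc_len))
  cat(sprintf("  head        : %d -> %d -> %d -> 2 (softmax)\n",
              x$desc_len, cfg$fc_sizes[1L], cfg$fc_sizes[2L]))
  cat(sprintf("  dropout     : %.0f%% conv / %.0f%% fc;  parameters: %d\n",
              100 * cfg$dropout_conv, 100 * cfg$dropout_fc, npar))
  invisible(x)
}

## ---- gather-based 3D convolution (same padding) ----

## base index matrix (l^3 x k^3): entry (p, n) is the flat spatial index of
## neighbor n of voxel p, or 0 when the neighbor falls in the zero padding
conv_gather_index <- function(l, k) {
  cache_get(sprintf("idx:%d:%d", l, k), function() {
    p <- (k - 1L) %/% 2L
    vox <- as.matrix(expand.grid(z = 1:l, y = 1:l, x = 1:l))
    offs <- as.matrix(expand.grid(dz = -p:p, dy = -p:p, dx = -p:p))
    l3 <- l^3L; k3 <- k^3L
    base <- matrix(0L, l3, k3)
    for (n in seq_len(k3)) {
      nb <- sweep(vox, 2L, offs[n, ], "+")
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= l & nb[, 2L] >= 1L & nb[, 2L] <= l &
            nb[, 3L] >= 1L & nb[, 3L] <= l
      base[ok, n] <- (nb[ok, 3L] - 1L) * l * l + (nb[ok, 2L] - 1L) * l + nb[ok, 1L]
    }
    base
  })
}

## batched gather index: rows (sample-blocked spatial positions), cols k^3;
## 0 marks padding
batch_gather_index <- function(base, B, l3) {
  k3 <- ncol(base)
  IDX <- outer(as.vector(base), (0:(B - 1L)) * l3, "+")
  IDX[as.vector(base) == 0L, ] <- 0L
  A <- array(IDX, c(l3, k3, B))
  A <- aperm(A, c(1L, 3L, 2L))
  dim(A) <- c(l3 * B, k3)
  A
}

## X: (B*l3) x C -> G: (B*l3) x (k3*C), neighbor fastest within channel
conv_gather <- function(X, A) {
  Xp <- rbind(0, X)
  G <- Xp[as.vector(A) + 1L, , drop = FALSE]
  dim(G) <- c(nrow(A), ncol(A) * ncol(X))
  G
}

## scatter-add the gradient of a gather back onto the input rows
conv_scatter <- function(dG, A, nrowX, C) {
  dG3 <- dG
  dim(dG3) <- c(nrow(A) * ncol(A), C)
  tgt <- as.vector(A)
  keep <- tgt > 0L
  acc <- rowsum(dG3[keep, , drop = FALSE], group = tgt[keep])
  dX <- matrix(0, nrowX, C)
  dX[as.integer(rownames(acc)), ] <- acc
  dX
}

## ---- spatial pyramid pooling bins ----

## adaptive bin membership (per level, k^3 bins of spatial indices); bin i
## along an axis covers floor((i-1)*m/k)+1 .. ceiling(i*m/k), so bins tile
## the input when k <= m and repeat voxels when k > m
spp_bin_ranges <- function(m, k) {
  lapply(seq_len(k), function(i) {
    s <- floor((i - 1L) * m / k) + 1L
    e <- ceiling(i * m / k)
    s:max(s, e)
  })
}

spp_bins <- function(m, levels) {
  cache_get(sprintf("bins:%d:%s", m, paste(levels, collapse = ",")), function() {
    out <- list()
    for (k in levels) {
      rng <- spp_bin_ranges(m, k)
      for (bx in seq_len(k)) for (by in seq_len(k)) for (bz in seq_len(k)) {
        g <- expand.grid(z = rng[[bz]], y = rng[[by]], x = rng[[bx]])
        out[[length(out) + 1L]] <-
          as.integer((g$x - 1L) * m * m + (g$y - 1L) * m + g$z)
      }
    }
    out
  })
}

#' Spatial pyramid pooling of a cubic feature map
#'
#' Pools each channel of a cubic feature map at every pyramid level into a
#' fixed `k^3` grid of adaptive bins, producing a descriptor whose length
#' (`channels x sum(levels^3)`) is independent of the input edge. Bins tile
#' the input when the level is coarser than the map and repeat voxels when
#' it is finer, so even an edge-3 patch feeds a level-4 grid.
#'
#' @param features cubic 3D array (one channel) or 4D array
#'   `(m, m, m, channels)`.
#' @param levels pyramid level edges (default `c(1, 2, 4)`).
#' @param pool `"max"` or `"mean"`.
#' @return Numeric descriptor vector, channel-major (all bins of channel 1,
#'   then channel 2, ...); within a channel, levels in order, bins in
#'   z-fastest order.
#' @export
spp_pool <- function(features, levels = c(1L, 2L, 4L), pool = c("max", "mean")) {
  pool <- match.arg(pool)
  dmf <- dim(features)
  if (length(dmf) == 3L) { dim(features) <- c(dmf, 1L); dmf <- dim(features) }
  if (length(dmf) != 4L || length(unique(dmf[1:3])) != 1L)
    stop("`features` must be a cubic 3D or 4D (m, m, m, channels) array")
  m <- dmf[1L]; C <- dmf[4L]
  X <- matrix(as.numeric(features), m^3L, C)
  res <- spp_pool_forward_cpp(X, 1L, m^3L, spp_bins(m, as.integer(levels)),
                              pool == "mean")
  as.numeric(res$desc)
}

## ---- forward / backward ----

relu <- function(x) { x[x < 0] <- 0; x }

dropout_mask <- function(nr, nc, p) {
  keep <- 1 - p
  matrix((runif(nr * nc) < keep) / keep, nr, nc)
}

## X: (B*l3) x 1 stacked normalized patches. Dropout masks are drawn from
## the current RNG stream (training mode only).
net_forward <- function(net, X, B, l, training = FALSE, keep_cache = FALSE) {
  cfg <- net$config
  l3 <- l^3L
  base <- conv_gather_index(l, cfg$kernel_edge)
  cache <- if (keep_cache) list(base = base, B = B, l = l,
                                conv = vector("list", 5L),
                                fc = vector("list", 3L)) else NULL
  H <- X
  for (i in seq_len(5L)) {
    Z <- conv_forward_cpp(H, base, net$conv[[i]]$W, net$conv[[i]]$b, B, l3)
    act <- relu(Z)
    M <- NULL
    if (training && cfg$dropout_conv > 0) {
      M <- dropout_mask(nrow(act), ncol(act), cfg$dropout_conv)
      act <- act * M
    }
    if (keep_cache)
      cache$conv[[i]] <- list(input = H, relu = Z > 0, drop = M)
    H <- act
  }
  bins <- spp_bins(l, cfg$spp_levels)
  pooled <- spp_pool_forward_cpp(H, B, l3, bins, cfg$pool == "mean")
  D <- pooled$desc   # B x (C5 * nbins)
  if (keep_cache) {
    cache$spp <- list(argmax = pooled$argmax, nrowX = nrow(H), C = ncol(H),
                      bins = bins)
  }
  Hf <- D
  for (i in 1:2) {
    Z <- Hf %*% net$fc[[i]]$W
    Z <- sweep(Z, 2L, net$fc[[i]]$b, "+")
    act <- relu(Z)
    M <- NULL
    if (training && cfg$dropout_fc > 0) {
      M <- dropout_mask(nrow(act), ncol(act), cfg$dropout_fc)
      act <- act * M
    }
    if (keep_cache) cache$fc[[i]] <- list(input = Hf, relu = Z > 0, drop = M)
    Hf <- act
  }
  logits <- sweep(Hf %*% net$fc[[3L]]$W, 2L, net$fc[[3L]]$b, "+")
  if (keep_cache) cache$fc[[3L]] <- list(input = Hf)
  shift <- logits - apply(logits, 1L, max)
  e <- exp(shift)
  prob <- e / rowSums(e)
  colnames(prob) <- c("root", "nonroot")
  list(prob = prob, cache = cache)
}

## gradient of the cross-entropy/softmax and all parameters; returns grads
## in the same shape as the network's parameter lists
net_backward <- function(net, cache, prob, y) {
  cfg <- net$config
  B <- nrow(prob)
  onehot <- matrix(0, B, 2L)
  onehot[cbind(seq_len(B), y)] <- 1
  dZ <- (prob - onehot) / B
  gfc <- vector("list", 3L)
  gfc[[3L]] <- list(W = crossprod(cache$fc[[3L]]$input, dZ), b = colSums(dZ))
  dH <- dZ %*% t(net$fc[[3L]]$W)
  for (i in 2:1) {
    if (!is.null(cache$fc[[i]]$drop)) dH <- dH * cache$fc[[i]]$drop
    dH <- dH * cache$fc[[i]]$relu
    gfc[[i]] <- list(W = crossprod(cache$fc[[i]]$input, dH), b = colSums(dH))
    dH <- dH %*% t(net$fc[[i]]$W)
  }
  ## through the pyramid pooling
  sp <- cache$spp
  dX5 <- if (cfg$pool == "mean")
    spp_pool_backward_mean_cpp(dH, cache$B, cache$l^3L, sp$bins, sp$C)
  else
    spp_pool_backward_max_cpp(dH, sp$argmax, sp$nrowX, sp$C)
  gconv <- vector("list", 5L)
  dA <- dX5
  for (i in 5:1) {
    cc <- cache$conv[[i]]
    if (!is.null(cc$drop)) dA <- dA * cc$drop
    dA <- dA * cc$relu
    bw <- conv_backward_cpp(cc$input, cache$base, net$conv[[i]]$W, dA,
                            cache$B, cache$l^3L)
    gconv[[i]] <- list(W = bw$gW, b = colSums(dA))
    dA <- bw$dX
  }
  list(conv = gconv, fc = gfc)
}

#' Classify a batch of cubic patches
#'
#' Runs the network in evaluation mode (dropout disabled, deterministic) on
#' a list of cubic gray patches sharing one edge length and returns the
#' two-class probabilities in input order. Mixed edge lengths must be split
#' into per-size batches by the caller.
#'
#' @param net an [build_network()] network.
#' @param patches list of cubic numeric 3D arrays with one common odd edge.
#' @return A data frame with columns `p_root`, `p_nonroot` (rows sum to 1),
#'   one row per patch; zero rows for an empty list.
#' @export
predict_batch <- function(net, patches) {
  stopifnot(inherits(net, "spp_net"))
  if (length(patches) == 0L)
    return(data.frame(p_root = numeric(0), p_nonroot = numeric(0)))
  edges <- vapply(patches, function(p) {
    d <- dim(p)
    if (is.null(d) || length(d) != 3L || length(unique(d)) != 1L)
      stop("patches must be cubic 3D arrays")
    d[1L]
  }, integer(1))
  if (length(unique(edges)) != 1L)
    stop("all patches in one batch must share one edge length")
  l <- edges[1L]
  if (l %% 2L == 0L) stop("patch edge must be odd")
  B <- length(patches)
  X <- matrix(0, B * l^3L, 1L)
  for (s in seq_len(B)) X[((s - 1L) * l^3L + 1L):(s * l^3L), 1L] <- as.numeric(patches[[s]])
  prob <- net_forward(net, X, B, l, training = FALSE)$prob
  data.frame(p_root = prob[, 1L], p_nonroot = prob[, 2L])
}

#' Z-score a gray volume
#'
#' Affine per-volume normalization to zero mean, unit variance, applied
#' before patch extraction.
#' @param vol a [gray_volume()].
#' @return A normalized [gray_volume()].
#' @export
normalize_volume <- function(vol) {
  stopifnot(inherits(vol, "gray_volume"))
  s <- stats::sd(vol$data)
  if (s == 0) s <- 1
  gray_volume((vol$data - mean(vol$data)) / s, vol$spacing_um)
}

#' Extract the cubic patch around a voxel
#' @param vol a [gray_volume()] (or [binary_volume()]).
#' @param center 1-based `(z, y, x)`.
#' @param r field-of-view radius; the patch must lie inside the volume.
#' @return Cubic array of edge `2r + 1`.
#' @export
extract_patch <- function(vol, center, r) {
  dat <- vol_data(vol)
  dm <- dim(dat)
  if (any(center - r < 1L) || any(center + r > dm))
    stop(sprintf("patch at (%s) with r=%d leaves the volume",
                 paste(center, collapse = ","), r))
  dat[(center[1L] - r):(center[1L] + r),
      (center[2L] - r):(center[2L] + r),
      (center[3L] - r):(center[3L] + r), drop = FALSE]
}

## stacked patch matrix for centers (k x 3), all at radius r
stack_patches <- function(dat, centers, r) {
  l <- 2L * r + 1L
  l3 <- l^3L
  B <- nrow(centers)
  X <- matrix(0, B * l3, 1L)
  for (s in seq_len(B)) {
    z <- centers[s, 1L]; y <- centers[s, 2L]; x <- centers[s, 3L]
    X[((s - 1L) * l3 + 1L):(s * l3), 1L] <-
      dat[(z - r):(z + r), (y - r):(y + r), (x - r):(x + r)]
  }
  X
}

#' Wrap a network as a voxel classifier over one volume
#'
#' Binds a trained network to a gray volume (normalizing it once if the
#' network config asks for it) and returns the classifier contract used by
#' [dynamic_infer()] and [naive_infer()]: `function(centers, r)` returning
#' the root probability of each 1-based `(z, y, x)` center at field-of-view
#' radius `r`. Large requests are evaluated in chunks.
#'
#' @param net an `spp_net`.
#' @param vol the [gray_volume()] to classify in.
#' @param chunk maximal patches per forward pass.
#' @return A function `(centers, r) -> numeric p_root`.
#' @export
network_classifier <- function(net, vol, chunk = 1024L) {
  stopifnot(inherits(net, "spp_net"), inherits(vol, "gray_volume"))
  dat <- if (net$config$normalize) normalize_volume(vol)$data else vol$data
  function(centers, r) {
    centers <- rbind(centers)
    n <- nrow(centers)
    if (n == 0L) return(numeric(0))
    l <- 2L * r + 1L
    out <- numeric(n)
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(n, start + chunk - 1L)
      X <- stack_patches(dat, centers[idx, , drop = FALSE], r)
      out[idx] <- net_forward(net, X, length(idx), l)$prob[, 1L]
    }
    out
  }
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the full [net_config()] alongside the weights.
#' @param net an `spp_net`.
#' @param path checkpoint file.
#' @return `load_network` returns the `spp_net`; `save_network` returns
#'   `path` invisibly.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "spp_net"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "spp_net")) stop("not a network checkpoint")
  net
}
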