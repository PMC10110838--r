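## Training: single-cycle cosine-annealed SGD over a sub-label-balanced
## sample set, and the weakly supervised loop that retrains from scratch on
## its own relabelings.

#' Cosine annealing learning rate
#'
#' Single-cycle cosine schedule
#' `eta_t = 0.5 * eta0 * (1 + cos(pi * t / T))`: the rate starts at `eta0`,
#' halves at `t = T/2` and reaches 0 at `t = T`.
#'
#' @param t step index, `0 <= t <= T` (vectorized).
#' @param T total step count (>= 1).
#' @param eta0 initial learning rate (> 0).
#' @return The learning rate(s) at `t`.
#' @examples
#' cosine_lr(c(0, 5, 10), 10, 0.1)
#' @export
cosine_lr <- function(t, T, eta0) {
  if (T < 1) stop("`T` must be >= 1")
  if (eta0 <= 0) stop("`eta0` must be > 0")
  if (any(t < 0) || any(t > T)) stop("`t` must satisfy 0 <= t <= T")
  0.5 * eta0 * (1 + cos(pi * t / T))
}

#' Total schedule steps for a sample count
#'
#' One schedule step spans `f` batches of size `b`; a single pass over `n`
#' samples therefore takes `T = ceiling(n / (b * f))` steps (ceiling so the
#' rate reaches its floor only at or after the last sample).
#'
#' @param n_samples training sample count.
#' @param b batch size.
#' @param f schedule update frequency in batches.
#' @return Integer `T >= 1`.
#' @export
schedule_length <- function(n_samples, b, f) {
  if (n_samples < 1 || b < 1 || f < 1) stop("all arguments must be >= 1")
  as.integer(ceiling(n_samples / (b * f)))
}

#' Training configuration
#'
#' The reference settings for full-scale runs are a batch size of 256 and a
#' schedule update every 4,000 batches; desk-scale runs shrink both (for
#' example `batch_size = 64`, `update_frequency = 10`) while preserving the
#' `T = ceiling(n / (b f))` schedule semantics.
#'
#' @param batch_size samples per gradient step.
#' @param update_frequency schedule steps every this many batches.
#' @param eta0 initial learning rate of the cosine schedule.
#' @param iterations weak-loop cycle count (default 3).
#' @param optimizer `"sgd"` (momentum SGD, the only supported optimizer).
#' @param momentum SGD momentum coefficient.
#' @param loss `"cross-entropy"` (the only supported loss).
#' @param seed integer seed governing initialization, sample order and
#'   dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 256L, update_frequency = 4000L,
                         eta0 = 0.05, iterations = 3L, optimizer = "sgd",
                         momentum = 0.9, loss = "cross-entropy", seed = 1L) {
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (update_frequency < 1L) stop("`update_frequency` must be >= 1")
  if (eta0 <= 0) stop("`eta0` must be > 0")
  if (iterations < 1L) stop("`iterations` must be >= 1")
  if (!identical(optimizer, "sgd")) stop("only 'sgd' is supported")
  if (!identical(loss, "cross-entropy")) stop("only 'cross-entropy' is supported")
  structure(list(batch_size = as.integer(batch_size),
                 update_frequency = as.integer(update_frequency),
                 eta0 = eta0, iterations = as.integer(iterations),
                 optimizer = optimizer, momentum = momentum, loss = loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

as_volume_list <- function(volumes, default_name = "vol") {
  if (inherits(volumes, c("gray_volume", "binary_volume")))
    volumes <- stats::setNames(list(volumes), default_name)
  if (is.null(names(volumes)) || any(names(volumes) == ""))
    stop("volume lists must be named")
  volumes
}

check_sample_margins <- function(samples, volumes) {
  for (i in seq_len(nrow(samples))) {
    dm <- dim(vol_data(volumes[[samples$volume[i]]]))
    r <- samples$r[i]
    zyx <- c(samples$z[i], samples$y[i], samples$x[i])
    if (any(zyx - r < 1L) || any(zyx + r > dm))
      stop(sprintf("sample at (%d, %d, %d) with r=%d violates the interior margin",
                   zyx[1L], zyx[2L], zyx[3L], r))
  }
  invisible(TRUE)
}

eval_loss <- function(net, dats, samples, chunk = 512L) {
  total <- 0
  n <- nrow(samples)
  for (rr in unique(samples$r)) {
    sub <- samples[samples$r == rr, , drop = FALSE]
    for (start in seq(1L, nrow(sub), by = chunk)) {
      idx <- start:min(nrow(sub), start + chunk - 1L)
      blk <- sub[idx, , drop = FALSE]
      for (vid in unique(blk$volume)) {
        bv <- blk[blk$volume == vid, , drop = FALSE]
        X <- stack_patches(dats[[vid]], as.matrix(bv[, c("z", "y", "x")]), rr)
        prob <- net_forward(net, X, nrow(bv), 2L * rr + 1L)$prob
        y <- ifelse(bv$class == "root", 1L, 2L)
        total <- total + sum(-log(pmax(prob[cbind(seq_len(nrow(bv)), y)], 1e-12)))
      }
    }
  }
  total / n
}

#' Train a network once on a balanced sample set
#'
#' One pass of momentum SGD over the sample set with the single-cycle
#' cosine-annealed learning rate: batches are grouped by field-of-view edge
#' (the batching constraint of the pyramid network), the batch order is
#' shuffled, and the rate updates every `update_frequency` batches. The
#' binary target of each sample is its sub-label's center class. Runs are
#' deterministic for a given config.
#'
#' @param volumes a [gray_volume()] or named list of them; names must match
#'   `samples$volume`.
#' @param samples a `sample_set` from [balance_samples()].
#' @param cfg a [train_config()].
#' @param net_cfg a [net_config()].
#' @param val optional validation set: `list(volumes = ..., samples = ...)`
#'   in the same format; its loss is evaluated (dropout off) at every
#'   schedule step.
#' @return A list with `network`, `curves` (data frame: step, eta,
#'   train_loss, val_loss) and the configs.
#' @export
train_once <- function(volumes, samples, cfg, net_cfg = net_config(),
                       val = NULL) {
  stopifnot(inherits(cfg, "train_config"), inherits(net_cfg, "net_config"))
  volumes <- as_volume_list(volumes)
  if (nrow(samples) == 0L) stop("empty sample set")
  check_sample_margins(samples, volumes)
  dats <- lapply(volumes, function(v)
    if (net_cfg$normalize) normalize_volume(v)$data else v$data)
  val_dats <- NULL
  if (!is.null(val)) {
    vvol <- as_volume_list(val$volumes)
    check_sample_margins(val$samples, vvol)
    val_dats <- lapply(vvol, function(v)
      if (net_cfg$normalize) normalize_volume(v)$data else v$data)
  }
  b <- cfg$batch_size; f <- cfg$update_frequency
  n <- nrow(samples)
  T_total <- schedule_length(n, b, f)

  net <- build_network(net_cfg, seed = cfg$seed)
  vel <- list(conv = lapply(net$conv, function(ly) list(W = ly$W * 0, b = ly$b * 0)),
              fc = lapply(net$fc, function(ly) list(W = ly$W * 0, b = ly$b * 0)))

  curves <- NULL
  with_seed(cfg$seed + 1L, {
    ord <- sample.int(n)
    shuffled <- samples[ord, , drop = FALSE]
    ## batches grouped by FoV edge, then batch order shuffled
    batches <- list()
    for (rr in unique(shuffled$r)) {
      rows <- which(shuffled$r == rr)
      for (start in seq(1L, length(rows), by = b))
        batches[[length(batches) + 1L]] <- rows[start:min(length(rows), start + b - 1L)]
    }
    batches <- batches[sample.int(length(batches))]

    step_losses <- numeric(0)
    rec <- function(step, eta) {
      vl <- if (!is.null(val_dats)) eval_loss(net, val_dats, val$samples) else NA_real_
      tl <- if (length(step_losses)) mean(step_losses) else NA_real_
      curves <<- rbind(curves, data.frame(step = step, eta = eta,
                                          train_loss = tl, val_loss = vl))
    }
    cur_step <- 0L
    for (bi in seq_along(batches)) {
      t_idx <- (bi - 1L) %/% f
      if (t_idx > cur_step) {           # schedule step boundary
        rec(cur_step, cosine_lr(cur_step, T_total, cfg$eta0))
        step_losses <- numeric(0)
        cur_step <- t_idx
      }
      eta <- cosine_lr(min(t_idx, T_total), T_total, cfg$eta0)
      rows <- batches[[bi]]
      blk <- shuffled[rows, , drop = FALSE]
      rr <- blk$r[1L]
      l <- 2L * rr + 1L
      ## per-volume sub-stacks, order preserved
      X <- matrix(0, nrow(blk) * l^3L, 1L)
      for (vid in unique(blk$volume)) {
        sel <- which(blk$volume == vid)
        Xv <- stack_patches(dats[[vid]], as.matrix(blk[sel, c("z", "y", "x")]), rr)
        for (q in seq_along(sel)) {
          s <- sel[q]
          X[((s - 1L) * l^3L + 1L):(s * l^3L), 1L] <-
            Xv[((q - 1L) * l^3L + 1L):(q * l^3L), 1L]
        }
      }
      fw <- net_forward(net, X, nrow(blk), l, training = TRUE, keep_cache = TRUE)
      y <- ifelse(blk$class == "root", 1L, 2L)
      loss <- mean(-log(pmax(fw$prob[cbind(seq_len(nrow(blk)), y)], 1e-12)))
      step_losses <- c(step_losses, loss)
      gr <- net_backward(net, fw$cache, fw$prob, y)
      for (i in seq_len(5L)) {
        vel$conv[[i]]$W <- cfg$momentum * vel$conv[[i]]$W - eta * gr$conv[[i]]$W
        vel$conv[[i]]$b <- cfg$momentum * vel$conv[[i]]$b - eta * gr$conv[[i]]$b
        net$conv[[i]]$W <- net$conv[[i]]$W + vel$conv[[i]]$W
        net$conv[[i]]$b <- net$conv[[i]]$b + vel$conv[[i]]$b
      }
      for (i in seq_len(3L)) {
        vel$fc[[i]]$W <- cfg$momentum * vel$fc[[i]]$W - eta * gr$fc[[i]]$W
        vel$fc[[i]]$b <- cfg$momentum * vel$fc[[i]]$b - eta * gr$fc[[i]]$b
        net$fc[[i]]$W <- net$fc[[i]]$W + vel$fc[[i]]$W
        net$fc[[i]]$b <- net$fc[[i]]$b + vel$fc[[i]]$b
      }
    }
    rec(cur_step, cosine_lr(min(cur_step, T_total), T_total, cfg$eta0))
  })
  list(network = net, curves = curves, train_config = cfg, net_config = net_cfg)
}

#' Weakly supervised training loop
#'
#' Recursive self-training: in each cycle the current label volumes drive
#' the sub-label categorization, a balanced sample set is drawn, a fresh
#' network is trained from scratch, and the network's own dynamic-inference
#' segmentation of the training volumes replaces the labels for the next
#' cycle. Generalization tends to smooth label noise, so labels typically
#' improve over cycles; the final network is the last cycle's.
#'
#' @param volumes a [gray_volume()] or named list of them.
#' @param labels0 initial weak label [binary_volume()](s) aligned with
#'   `volumes` (e.g. an analytical pre-segmentation, or phantom labels
#'   corrupted with [corrupt_labels()]).
#' @param sediment sediment mask(s) used by the sub-labeling, fixed across
#'   cycles.
#' @param cfg a [train_config()]; `cfg$iterations` cycles are run.
#' @param net_cfg a [net_config()].
#' @param infer_cfg an [infer_config()]; its `seeds` may be a matrix (one
#'   volume) or a named list of matrices.
#' @param spec a [distribution_spec()] for the balanced draws; the draw
#'   seed is offset by the cycle index.
#' @param val optional validation set as in [train_once()].
#' @return A `weak_loop_record`: list with `networks`, `labels`
#'   (`L_0 ... L_final`), `curves` per cycle, and the configs.
#' @export
weak_loop <- function(volumes, labels0, sediment, cfg, net_cfg, infer_cfg,
                      spec, val = NULL) {
  volumes <- as_volume_list(volumes)
  labels <- as_volume_list(labels0)
  sediment <- as_volume_list(sediment)
  stopifnot(identical(sort(names(volumes)), sort(names(labels))))
  seeds_by_vol <- infer_cfg$seeds
  if (!is.list(seeds_by_vol)) seeds_by_vol <-
    stats::setNames(rep(list(seeds_by_vol), length(volumes)), names(volumes))
  radii <- sort(unique(spec$r))
  networks <- list(); curves <- list()
  label_hist <- list(labels)
  for (iter in seq_len(cfg$iterations)) {
    tables <- list()
    for (vid in names(volumes)) {
      ## noisy labels may claim voxels of the fixed sediment mask; a voxel
      ## currently labeled root cannot simultaneously count as sediment
      sed <- binary_volume(array(
        as.integer(sediment[[vid]]$data == 1L & labels[[vid]]$data == 0L),
        dim(sediment[[vid]]$data)))
      for (rr in radii) {
        tables[[length(tables) + 1L]] <-
          build_sample_table(labels[[vid]], sed, rr, volume_id = vid)
      }
    }
    spec_i <- spec
    attr(spec_i, "seed") <- attr(spec, "seed") + (iter - 1L)
    samples <- suppressWarnings(balance_samples(tables, spec_i))
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + 1000L * (iter - 1L)   # fresh network each cycle
    fit <- train_once(volumes, samples, cfg_i, net_cfg, val = val)
    networks[[iter]] <- fit$network
    curves[[iter]] <- fit$curves
    new_labels <- labels
    for (vid in names(volumes)) {
      ci <- infer_cfg
      ci$seeds <- seeds_by_vol[[vid]]
      seg <- suppressWarnings(
        dynamic_infer(volumes[[vid]],
                      network_classifier(fit$network, volumes[[vid]]), ci))
      if (is.null(seg) || sum(seg$roots$data) == 0L) {
        warning(sprintf("cycle %d: dynamic inference of '%s' returned an empty segmentation; keeping previous labels",
                        iter, vid))
      } else {
        new_labels[[vid]] <- seg$roots
      }
    }
    labels <- new_labels
    label_hist[[iter + 1L]] <- labels
  }
  structure(list(networks = networks, labels = label_hist, curves = curves,
                 train_config = cfg, net_config = net_cfg,
                 infer_config = infer_cfg),
            class = "weak_loop_record")
}
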