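test_that("the default architecture matches the reference design", {
  net <- build_network(net_config(), seed = 1L)
  expect_identical(length(net$conv), 5L)
  expect_identical(net$config$kernel_edge, 5L)
  expect_identical(net$config$spp_levels, c(1L, 2L, 4L))
  expect_identical(spp_descriptor_bins(net$config$spp_levels), 73L)
  expect_true(all(diff(net$config$conv_channels) > 0L))
  expect_identical(net$config$dropout_conv, 0.40)
  expect_identical(net$config$dropout_fc, 0.70)
  # descriptor length = channels of last stage x 73; head ends in 2 classes
  expect_identical(net$desc_len, net$config$conv_channels[5L] * 73L)
  expect_identical(ncol(net$fc[[3L]]$W), 2L)
  expect_error(net_config(conv_channels = c(8L, 8L, 16L, 32L, 64L)), "increasing")
  expect_error(net_config(kernel_edge = 4L), "odd")
})

test_that("network initialization is seeded and uses zero biases", {
  a <- build_network(net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L)), seed = 5L)
  b <- build_network(net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L)), seed = 5L)
  d <- build_network(net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L)), seed = 6L)
  expect_identical(a$conv[[1L]]$W, b$conv[[1L]]$W)
  expect_false(identical(a$conv[[1L]]$W, d$conv[[1L]]$W))
  for (ly in c(a$conv, a$fc)) expect_true(all(ly$b == 0))
})

test_that("spp_pool yields a size-invariant descriptor across edges 3..15", {
  cfgs <- list(c(1L, 2L, 4L), c(1L, 3L))
  for (levels in cfgs) {
    lens <- integer(0)
    for (l in seq(3L, 15L, by = 2L)) {
      set.seed(l)
      f <- array(rnorm(l^3 * 2), c(l, l, l, 2L))
      lens <- c(lens, length(spp_pool(f, levels)))
    }
    expect_identical(unique(lens), 2L * spp_descriptor_bins(levels))
  }
})

test_that("spp_pool agrees with direct bin-wise pooling", {
  set.seed(21)
  for (m in c(3L, 5L)) {
    f <- array(rnorm(m^3 * 2), c(m, m, m, 2L))
    levels <- c(1L, 2L, 4L)
    got <- spp_pool(f, levels, pool = "max")
    want <- numeric(0)
    for (ch in 1:2) {
      for (k in levels) {
        # package bin order within a level: z fastest, then y, then x
        for (bx in seq_len(k)) for (by in seq_len(k)) for (bz in seq_len(k)) {
          cell <- f[oracle_bin_range(m, k, bz), oracle_bin_range(m, k, by),
                    oracle_bin_range(m, k, bx), ch]
          want <- c(want, max(cell))
        }
      }
    }
    expect_equal(got, want)
    # mean pooling over the level-1 bin is the channel mean
    gm <- spp_pool(f, c(1L), pool = "mean")
    expect_equal(gm, c(mean(f[, , , 1L]), mean(f[, , , 2L])))
  }
})

test_that("the gather convolution equals the direct zero-padded convolution", {
  set.seed(31)
  l <- 5L; k <- 3L; C_in <- 2L; C_out <- 3L
  X <- matrix(rnorm(l^3 * C_in), l^3, C_in)
  W <- matrix(rnorm(k^3 * C_in * C_out), k^3 * C_in, C_out)
  b <- rnorm(C_out)
  A <- rootfill:::conv_gather_index(l, k)
  G <- rootfill:::conv_gather(X, rootfill:::batch_gather_index(A, 1L, l^3))
  Z <- sweep(G %*% W, 2L, b, "+")
  for (i in 1:12) {
    pos <- c(sample(l, 1L), sample(l, 1L), sample(l, 1L))
    flat <- (pos[3L] - 1L) * l^2 + (pos[2L] - 1L) * l + pos[1L]
    co <- sample(C_out, 1L)
    expect_equal(Z[flat, co], oracle_conv_at(X, W, b, pos, l, k, co))
  }
  # the compiled batched gather/scatter equal the plain-R reference
  B <- 3L
  Xb <- matrix(rnorm(B * l^3 * C_in), B * l^3, C_in)
  Ab <- rootfill:::batch_gather_index(A, B, l^3)
  Gb <- rootfill:::conv_gather(Xb, Ab)
  expect_equal(rootfill:::conv_gather_batched_cpp(Xb, A, B, l^3L), Gb)
  dG <- matrix(rnorm(length(Gb)), nrow(Gb), ncol(Gb))
  expect_equal(rootfill:::conv_scatter_batched_cpp(dG, A, B, l^3L),
               rootfill:::conv_scatter(dG, Ab, nrow(Xb), C_in))
})

test_that("analytic gradients match finite differences", {
  set.seed(4)
  cfg <- net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L), kernel_edge = 3L,
                    fc_sizes = c(8L, 6L), dropout_conv = 0, dropout_fc = 0)
  net <- build_network(cfg, seed = 5L)
  B <- 2L; l <- 5L
  X <- matrix(rnorm(B * l^3), B * l^3, 1L)
  y <- c(1L, 2L)
  lossfun <- function(net) {
    fw <- rootfill:::net_forward(net, X, B, l)
    -mean(log(pmax(fw$prob[cbind(seq_len(B), y)], 1e-12)))
  }
  fw <- rootfill:::net_forward(net, X, B, l, keep_cache = TRUE)
  gr <- rootfill:::net_backward(net, fw$cache, fw$prob, y)
  eps <- 1e-5
  for (spec in list(list(\(n) n$conv[[1L]], \(n, p) { n$conv[[1L]] <- p; n }, gr$conv[[1L]]),
                    list(\(n) n$conv[[5L]], \(n, p) { n$conv[[5L]] <- p; n }, gr$conv[[5L]]),
                    list(\(n) n$fc[[2L]],   \(n, p) { n$fc[[2L]] <- p; n },   gr$fc[[2L]]))) {
    layer <- spec[[1L]](net)
    for (i in sample(length(layer$W), 4L)) {
      up <- layer; up$W[i] <- up$W[i] + eps
      dn <- layer; dn$W[i] <- dn$W[i] - eps
      gnum <- (lossfun(spec[[2L]](net, up)) - lossfun(spec[[2L]](net, dn))) / (2 * eps)
      expect_equal(spec[[3L]]$W[i], gnum, tolerance = 1e-5)
    }
  }
})

test_that("predict_batch accepts edges 3..15 and returns proper probabilities", {
  net <- build_network(net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L),
                                  kernel_edge = 3L, fc_sizes = c(8L, 6L)),
                       seed = 2L)
  for (l in seq(3L, 15L, by = 2L)) {
    set.seed(l)
    patches <- lapply(1:3, function(i) array(rnorm(l^3), c(l, l, l)))
    p <- predict_batch(net, patches)
    expect_identical(dim(p), c(3L, 2L))
    expect_equal(p$p_root + p$p_nonroot, rep(1, 3))
    expect_true(all(p$p_root >= 0 & p$p_root <= 1))
  }
  # evaluation mode is deterministic even with dropout configured
  net2 <- build_network(net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L),
                                   kernel_edge = 3L, fc_sizes = c(8L, 6L),
                                   dropout_conv = 0.4, dropout_fc = 0.7),
                        seed = 2L)
  set.seed(1)
  patch <- list(array(rnorm(27), c(3L, 3L, 3L)))
  expect_identical(predict_batch(net2, patch), predict_batch(net2, patch))
  expect_identical(nrow(predict_batch(net, list())), 0L)
  expect_error(predict_batch(net, list(array(0, c(3L, 3L, 5L)))), "cubic")
  expect_error(predict_batch(net, list(array(0, c(3L, 3L, 3L)),
                                       array(0, c(5L, 5L, 5L)))), "edge")
  expect_error(predict_batch(net, list(array(0, c(4L, 4L, 4L)))), "odd")
})

test_that("network checkpoints round-trip", {
  net <- build_network(net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L),
                                  kernel_edge = 3L, fc_sizes = c(8L, 6L)),
                       seed = 3L)
  path <- file.path(tempdir(), "net.rds")
  save_network(net, path)
  back <- load_network(path)
  expect_identical(back, net)
  saveRDS(list(1), path)
  expect_error(load_network(path), "checkpoint")
})

test_that("network_classifier honors the classifier contract", {
  ph <- phantom64()
  net <- build_network(net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L),
                                  kernel_edge = 3L, fc_sizes = c(8L, 6L)),
                       seed = 3L)
  cls <- network_classifier(net, ph$gray)
  ctr <- rbind(c(20L, 30L, 30L), c(25L, 32L, 32L))
  p <- cls(ctr, 2L)
  expect_identical(length(p), 2L)
  expect_true(all(p >= 0 & p <= 1))
  # chunking does not change results
  cls1 <- network_classifier(net, ph$gray, chunk = 1L)
  expect_equal(cls1(ctr, 2L), p)
  # matches predict_batch on the normalized patches
  nv <- normalize_volume(ph$gray)
  pb <- predict_batch(net, list(extract_patch(nv, ctr[1L, ], 2L),
                                extract_patch(nv, ctr[2L, ], 2L)))
  expect_equal(pb$p_root, p)
})
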