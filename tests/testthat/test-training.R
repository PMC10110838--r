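test_that("the cosine schedule matches its closed form exactly", {
  eta0 <- 0.05
  for (T in c(1L, 7L, 4000L)) {
    expect_equal(cosine_lr(0, T, eta0), eta0, tolerance = 1e-12)
    expect_equal(cosine_lr(T / 2, T, eta0), eta0 / 2, tolerance = 1e-12)
    expect_equal(cosine_lr(T, T, eta0), 0, tolerance = 1e-12)
  }
  # vectorized and monotone decreasing over the cycle
  ts <- seq(0, 10, by = 0.5)
  expect_true(all(diff(cosine_lr(ts, 10, 0.1)) < 0))
  expect_error(cosine_lr(-1, 10, 0.1), "0 <= t <= T")
  expect_error(cosine_lr(11, 10, 0.1), "0 <= t <= T")
  expect_error(cosine_lr(1, 0, 0.1), ">= 1")
  expect_error(cosine_lr(1, 10, 0), "> 0")
})

test_that("schedule length is ceiling(n / (b f))", {
  expect_identical(schedule_length(256L * 4000L, 256L, 4000L), 1L)
  expect_identical(schedule_length(1L, 256L, 4000L), 1L)
  expect_identical(schedule_length(10L * 256L * 4000L, 256L, 4000L), 10L)
  expect_identical(schedule_length(256L * 4000L + 1L, 256L, 4000L), 2L)
  expect_identical(schedule_length(640L, 64L, 10L), 1L)
  expect_error(schedule_length(0L, 1L, 1L), ">= 1")
})

test_that("train_config validates its fields", {
  cfg <- train_config()
  expect_identical(cfg$batch_size, 256L)
  expect_identical(cfg$update_frequency, 4000L)
  expect_identical(cfg$iterations, 3L)
  expect_identical(cfg$optimizer, "sgd")
  expect_identical(cfg$loss, "cross-entropy")
  expect_error(train_config(optimizer = "adam"), "sgd")
  expect_error(train_config(loss = "hinge"), "cross-entropy")
  expect_error(train_config(batch_size = 0L), ">= 1")
  expect_error(train_config(eta0 = -1), "> 0")
})

separable_setup <- function(seed = 9L) {
  with_seed(seed, {
    dm <- c(18L, 18L, 18L)
    arr <- array(runif(prod(dm), 0, 0.3), dm)
    grid <- as.matrix(expand.grid(z = 3:16, y = 3:16, x = 3:16))
    idx <- sample(nrow(grid), 1200L)
    cls <- rep(c("root", "nonroot"), length.out = 1200L)
    for (q in which(cls == "root")) {
      p <- grid[idx[q], ]
      arr[p[1L], p[2L], p[3L]] <- runif(1, 0.7, 1)
    }
    samples <- data.frame(volume = "v", sublabel = ifelse(cls == "root",
                                                          "root-else", "else-else"),
                          class = cls, r = 1L,
                          z = grid[idx, 1L], y = grid[idx, 2L], x = grid[idx, 3L],
                          stringsAsFactors = FALSE)
    list(vol = gray_volume(arr, spacing_um = 100), samples = samples)
  })
}

test_that("train_once learns a separable center-intensity task", {
  sep <- separable_setup()
  ncfg <- net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L), kernel_edge = 3L,
                     fc_sizes = c(8L, 6L), dropout_conv = 0, dropout_fc = 0)
  cfg <- train_config(batch_size = 16L, update_frequency = 3L, eta0 = 0.02,
                      seed = 2L)
  fit <- train_once(list(v = sep$vol), sep$samples, cfg, ncfg)
  # schedule bookkeeping: T = ceiling(1200 / 48) = 25, eta follows the cosine
  T_total <- schedule_length(nrow(sep$samples), 16L, 3L)
  expect_identical(T_total, 25L)
  expect_equal(fit$curves$eta, cosine_lr(fit$curves$step, T_total, 0.02))
  # the trained net separates held-out style predictions by center intensity
  cls <- network_classifier(fit$network, sep$vol)
  ctr <- as.matrix(sep$samples[, c("z", "y", "x")])
  p <- cls(ctr, 1L)
  acc <- mean((p >= 0.5) == (sep$samples$class == "root"))
  expect_gt(acc, 0.9)
  # training reduced the loss over the schedule
  tl <- fit$curves$train_loss
  tl <- tl[!is.na(tl)]
  expect_lt(tl[length(tl)], tl[1L])
})

test_that("training is deterministic and validation losses are recorded", {
  sep <- separable_setup()
  ncfg <- net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L), kernel_edge = 3L,
                     fc_sizes = c(8L, 6L), dropout_conv = 0.05, dropout_fc = 0.1)
  cfg <- train_config(batch_size = 32L, update_frequency = 2L, eta0 = 0.015,
                      seed = 7L)
  val <- list(volumes = list(v = sep$vol),
              samples = sep$samples[seq(1L, 1200L, by = 40L), , drop = FALSE])
  f1 <- train_once(list(v = sep$vol), sep$samples, cfg, ncfg, val = val)
  f2 <- train_once(list(v = sep$vol), sep$samples, cfg, ncfg, val = val)
  expect_identical(f1$network, f2$network)
  expect_identical(f1$curves, f2$curves)
  expect_true(all(is.finite(f1$curves$val_loss)))
  # a different seed gives a different network
  cfg3 <- cfg; cfg3$seed <- 8L
  f3 <- train_once(list(v = sep$vol), sep$samples, cfg3, ncfg)
  expect_false(identical(f1$network$conv[[1L]]$W, f3$network$conv[[1L]]$W))
})

test_that("margin violations are rejected with the offending coordinate", {
  sep <- separable_setup()
  bad <- sep$samples
  bad$z[3L] <- 1L
  cfg <- train_config(batch_size = 16L, update_frequency = 3L, seed = 2L)
  expect_error(
    train_once(list(v = sep$vol), bad, cfg,
               net_config(conv_channels = c(2L, 3L, 4L, 5L, 6L),
                          kernel_edge = 3L, fc_sizes = c(8L, 6L))),
    sprintf("\\(1, %d, %d\\)", bad$y[3L], bad$x[3L]))
  expect_error(train_once(list(v = sep$vol), sep$samples[0L, ], cfg,
                          net_config()), "empty")
})

test_that("weak_loop keeps its record contract with one cycle", {
  ph <- fixture("wl_phantom", function() generate_phantom(
    phantom_config(shape = c(48L, 48L, 48L), seed = 31L)))
  noisy <- corrupt_labels(ph$roots, ph$branch_index,
                          label_noise_config(seed = 31L),
                          sediment = ph$sediment)
  radii <- c(1L, 2L)
  # the corrupted labels may overlap the sediment mask; sub-labeling requires
  # disjoint masks, so the spec sizing uses sediment minus the noisy labels
  sed <- binary_volume(array(
    as.integer(ph$sediment$data == 1L & noisy$data == 0L), dim(noisy$data)))
  tabs <- lapply(radii, function(r) build_sample_table(noisy, sed, r, "v"))
  spec <- availability_balanced_spec(tabs, radii, 400L, seed = 3L)
  ncfg <- tiny_net_config()
  cfg <- train_config(batch_size = 64L, update_frequency = 10L, eta0 = 0.015,
                      iterations = 1L, seed = 11L)
  icfg <- infer_config(seeds = ph$seeds, fov_ladder = c(2L, 1L), theta = 0.5)
  rec <- suppressWarnings(
    weak_loop(list(v = ph$gray), list(v = noisy), list(v = ph$sediment),
              cfg, ncfg, icfg, spec))
  expect_s3_class(rec, "weak_loop_record")
  expect_identical(length(rec$networks), 1L)
  expect_identical(length(rec$labels), 2L)
  # L_0 is the unmodified input labeling
  expect_identical(rec$labels[[1L]]$v$data, noisy$data)
  # the relabeling is a genuine binary volume on the same grid
  expect_s3_class(rec$labels[[2L]]$v, "binary_volume")
  expect_identical(dim(rec$labels[[2L]]$v$data), dim(ph$roots$data))
  # the cycle's network was trained from a fresh initialization
  init <- build_network(ncfg, seed = cfg$seed)
  expect_false(identical(rec$networks[[1L]]$conv[[1L]]$W, init$conv[[1L]]$W))
})
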