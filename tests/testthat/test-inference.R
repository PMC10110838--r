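relabel_first_seen <- function(lab) {
  fg <- lab[lab > 0L]
  as.integer(factor(fg, levels = unique(fg)))
}

test_that("infer_config validates its fields", {
  cfg <- infer_config(seeds = c(1L, 2L, 3L))
  expect_identical(cfg$fov_ladder, c(7L, 3L, 2L, 1L))
  expect_identical(nrow(cfg$seeds), 1L)
  expect_error(infer_config(c(1L, 1L, 1L), fov_ladder = c(3L, 3L, 1L)),
               "strictly decreasing")
  expect_error(infer_config(c(1L, 1L, 1L), fov_ladder = c(2L, 1L, 0L)), ">= 1")
  expect_error(infer_config(c(1L, 1L, 1L), theta = 1), "theta")
  expect_error(infer_config(c(1L, 1L, 1L), connectivity = 18L), "6 or 26")
})

test_that("a perfect oracle recovers exactly the seed-connected ground truth", {
  ph <- phantom64()
  oracle <- make_oracle(ph$roots)
  for (conn in c(26L, 6L)) {
    want <- oracle_flood_fill(ph$roots$data, ph$seeds, conn)
    seg <- dynamic_infer(ph$gray, oracle,
                         infer_config(seeds = ph$seeds, theta = 0.5,
                                      connectivity = conn))
    expect_identical(seg$roots$data, want)
    # provenance covers exactly the root voxels
    expect_identical(seg$provenance > 0L, want == 1L)
  }
})

test_that("the segmentation is invariant to the batch size", {
  ph <- phantom64()
  oracle <- make_oracle(ph$roots, oracle_config(blur_weight = 0.3))
  segs <- lapply(c(1L, 16L, 4096L), function(mb)
    dynamic_infer(ph$gray, oracle,
                  infer_config(seeds = ph$seeds, fov_ladder = c(3L, 2L, 1L),
                               max_batch = mb)))
  expect_identical(segs[[1L]]$roots$data, segs[[2L]]$roots$data)
  expect_identical(segs[[2L]]$roots$data, segs[[3L]]$roots$data)
  expect_identical(segs[[1L]]$provenance, segs[[2L]]$provenance)
  expect_identical(segs[[2L]]$provenance, segs[[3L]]$provenance)
})

test_that("pruning converges to the smallest-FoV decision set", {
  ph <- phantom64()
  oracle <- make_oracle(ph$roots, oracle_config(blur_weight = 0.6))
  seg <- dynamic_infer(ph$gray, oracle,
                       infer_config(seeds = ph$seeds, fov_ladder = c(3L, 2L, 1L),
                                    theta = 0.5))
  want <- oracle_decision_set(dim(ph$roots$data), oracle, 1L, 0.5, ph$seeds)
  expect_identical(seg$roots$data, want)
})

test_that("evaluation counts are bounded by the ladder length per voxel", {
  ph <- phantom64()
  oracle <- make_oracle(ph$roots, oracle_config(blur_weight = 0.6))
  cfg <- infer_config(seeds = ph$seeds, fov_ladder = c(3L, 2L, 1L))
  seg <- dynamic_infer(ph$gray, oracle, cfg)
  expect_lte(seg$evaluations, 3L * prod(dim(ph$roots$data)))
  expect_gt(seg$evaluations, sum(seg$roots$data))
})

test_that("masks restrict both evaluation and growth", {
  ph <- phantom64()
  dm <- dim(ph$roots$data)
  half <- array(0L, dm)
  half[1:40, , ] <- 1L
  mask <- binary_volume(half)
  oracle <- make_oracle(ph$roots)
  seeds_in <- ph$seeds[ph$seeds[, 1L] <= 36L, , drop = FALSE]
  skip_if(nrow(seeds_in) == 0L)
  seg <- suppressWarnings(
    dynamic_infer(ph$gray, oracle,
                  infer_config(seeds = seeds_in, fov_ladder = c(3L, 2L, 1L),
                               mask = mask)))
  expect_true(all(seg$roots$data[41:64, , ] == 0L))
  # a voxel is evaluable only when its whole FoV fits inside the mask
  expect_true(all(seg$roots$data[40, , ] == 0L))
  expect_error(
    dynamic_infer(ph$gray, oracle,
                  infer_config(seeds = c(60L, 32L, 32L), mask = mask)),
    "inside the mask")
})

test_that("degenerate seed input is rejected or warned about", {
  ph <- phantom64()
  oracle <- make_oracle(ph$roots)
  cfg <- infer_config(seeds = matrix(integer(0), 0L, 3L))
  expect_error(dynamic_infer(ph$gray, oracle, cfg), "empty")
  expect_error(dynamic_infer(ph$gray, oracle,
                             infer_config(seeds = c(70L, 2L, 2L))),
               "inside the volume")
  # a seed in a non-root region yields an empty segmentation with a warning
  bg <- which(ph$roots$data == 0L & ph$sediment$data == 0L)
  ctr <- rootfill:::flat_to_zyx(bg[length(bg) %/% 2L], dim(ph$roots$data))
  ctr <- pmin(pmax(ctr, 8L), 56L)
  if (ph$roots$data[ctr] == 0L) {
    expect_warning(dynamic_infer(ph$gray, oracle,
                                 infer_config(seeds = ctr)), "empty")
  }
})

test_that("naive inference equals exhaustive thresholding on the interior", {
  ph <- phantom64()
  oracle <- make_oracle(ph$roots, oracle_config(blur_weight = 0.6))
  r <- 2L
  nv <- naive_infer(ph$gray, oracle, r, theta = 0.5)
  dm <- dim(ph$roots$data)
  want <- array(0L, dm)
  zi <- (r + 1L):(dm[1L] - r)
  centers <- as.matrix(expand.grid(z = zi, y = zi, x = zi))
  p <- oracle(centers, r)
  want[centers[p >= 0.5, , drop = FALSE]] <- 1L
  expect_identical(nv$data, want)
  # chunking does not change the result
  nv1 <- naive_infer(ph$gray, oracle, r, theta = 0.5, chunk = 1000L)
  expect_identical(nv1$data, nv$data)
})

test_that("component labeling matches the igraph reference", {
  set.seed(12)
  for (conn in c(6L, 26L)) {
    bin <- array(as.integer(runif(8^3) < 0.35), c(8L, 8L, 8L))
    got <- label_components(binary_volume(bin), conn)
    want <- oracle_components(bin, conn)
    expect_identical(got > 0L, want > 0L)
    expect_identical(relabel_first_seen(got), relabel_first_seen(want))
  }
})

test_that("cca_filter deletes components below min_size and keeps the rest", {
  dm <- c(6L, 30L, 6L)
  arr <- array(0L, dm)
  arr[3L, 1:9, 2L] <- 1L     # size 9
  arr[3L, 1:10, 5L] <- 1L    # size 10
  bin <- binary_volume(arr)
  filt <- cca_filter(bin, min_size = 10L)
  expect_identical(sum(filt$data), 10L)
  expect_true(all(filt$data[3L, 1:10, 5L] == 1L))
  # min_size = 1 keeps everything untouched
  expect_identical(cca_filter(bin, min_size = 1L), bin)
  expect_error(cca_filter(bin, min_size = 0L), ">= 1")
  # an empty volume passes through
  empty <- binary_volume(array(0L, dm))
  expect_identical(cca_filter(empty, min_size = 5L)$data, empty$data)
})

test_that("propose_seed returns the brightest voxel of the slab", {
  set.seed(3)
  arr <- array(runif(16^3, 0, 0.5), c(16L, 16L, 16L))
  arr[4L, 7L, 9L] <- 0.99       # inside the slab
  arr[12L, 2L, 2L] <- 1.0       # outside the slab
  vol <- gray_volume(arr, spacing_um = 100)
  expect_identical(as.integer(propose_seed(vol, 1:6)), c(4L, 7L, 9L))
  expect_identical(as.integer(propose_seed(vol, 1:16)), c(12L, 2L, 2L))
})
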