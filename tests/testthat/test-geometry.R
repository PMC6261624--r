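test_that("canonical layer stack discretizes the slab correctly", {
  st <- build_layer_stack(c(40, 40, 3.6), 0.4)
  expect_equal(st$nx, 100L)
  expect_equal(st$ny, 100L)
  expect_equal(nrow(st$slices), 9L)
  expect_equal(st$nx * st$ny * nrow(st$slices), 90000L)
  expect_equal(as.character(st$slices$kind),
               c("ENDO", "ISOLATION", "THICK_FIBROTIC", "THICK_FIBROTIC",
                 "THIN_FIBROTIC", "THICK_FIBROTIC", "THICK_FIBROTIC",
                 "ISOLATION", "EPI"))

  st2 <- build_layer_stack(c(8, 8, 3.6), 0.4)
  expect_equal(st2$nx * st2$ny * nrow(st2$slices), 3600L)

  expect_error(build_layer_stack(c(40, 40, 3.5), 0.4), "divisible")
  expect_error(build_layer_stack(c(40, 40, 4.0), 0.4), "canonical")
})

test_that("blob rasterization matches the per-element distance oracle", {
  st <- build_layer_stack()
  blob <- data.frame(x = 20, y = 20, radius = 2.5, kind = "MYOCARDIAL",
                     host_layer = 2L)
  mask <- rasterize_blobs(blob, st)
  # brute-force oracle over all element centers
  oracle <- matrix(FALSE, st$nx, st$ny)
  for (i in seq_len(st$nx)) {
    for (j in seq_len(st$ny)) {
      cx <- (i - 0.5) * 0.4; cy <- (j - 0.5) * 0.4
      oracle[i, j] <- (cx - 20)^2 + (cy - 20)^2 <= 2.5^2
    }
  }
  expect_identical(mask, oracle)
  expect_gt(sum(mask), 0)

  expect_false(any(rasterize_blobs(blob[0, ], st)))
  # coincident blobs: union idempotent
  expect_identical(rasterize_blobs(rbind(blob, blob), st), mask)
})

test_that("blob sampling is balanced, deterministic, and size-checked", {
  st <- build_layer_stack()
  set.seed(42)
  b1 <- sample_blob_set(st, 26, 2.6, "FIBROTIC")
  expect_equal(nrow(b1), 26)
  expect_true(all(b1$x >= 1.3 & b1$x <= 38.7))
  expect_true(all(b1$y >= 1.3 & b1$y <= 38.7))
  ctr <- c(mean(b1$x), mean(b1$y))
  expect_lt(sqrt(sum((ctr - 20)^2)), 4 + 1e-12)
  set.seed(42)
  b2 <- sample_blob_set(st, 26, 2.6, "FIBROTIC")
  expect_identical(b1, b2)
  # a single blob is trivially balanced
  set.seed(1)
  expect_equal(nrow(sample_blob_set(st, 1, 2.5, "MYOCARDIAL")), 1)
})

test_that("projection constraint empties the fibrotic/myocardial overlap", {
  st <- build_layer_stack()
  set.seed(7)
  myo <- sample_blob_set(st, 9, 2.5, "MYOCARDIAL")
  iso_mask <- rasterize_blobs(myo, st)
  # place a fibrotic blob right on a myocardial patch
  fib <- data.frame(x = myo$x[1], y = myo$y[1], radius = 2.6,
                    kind = "FIBROTIC", host_layer = 3L)
  fixed <- enforce_projection_constraint(fib, iso_mask, st)
  inter <- rasterize_blobs(fixed, st) & iso_mask
  expect_equal(sum(inter), 0)
  # no myocardial patches: input unchanged
  empty_mask <- matrix(FALSE, st$nx, st$ny)
  expect_identical(enforce_projection_constraint(fib, empty_mask, st), fib)
})

test_that("thin fibrotic mask is the element-wise intersection", {
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  m2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_identical(derive_thin_fibrotic_mask(m1, m1), m1)
  expect_false(any(derive_thin_fibrotic_mask(m1, !m1)))
  set.seed(3)
  r1 <- matrix(runif(400) < 0.4, 20, 20)
  r2 <- matrix(runif(400) < 0.4, 20, 20)
  expect_identical(derive_thin_fibrotic_mask(r1, r2), r1 & r2)
  expect_error(derive_thin_fibrotic_mask(m1, matrix(TRUE, 3, 3)), "shape")
})

test_that("IFD and EDD implement the fibrotic-fraction definitions", {
  st <- build_layer_stack(c(8, 8, 3.6), 0.4)
  labels <- array(1L, dim = c(20, 20, 9))
  g <- structure(list(stack = st, labels = labels), class = "fs_slab_geometry")
  expect_equal(compute_ifd(g), 0)
  expect_equal(compute_edd(g), 0)
  # all fibrotic-layer elements fibrotic
  labels[, , 3:7] <- 2L
  labels[, , 5] <- 2L
  g$labels <- labels
  expect_equal(compute_ifd(g), 100)
  # half the isolation elements fibrotic
  labels[, 1:10, c(2, 8)] <- 3L
  g$labels <- labels
  expect_equal(compute_edd(g), 50)
})

test_that("IFD computed from labels equals IFD from mask sums", {
  cfg <- group_config("STOCHASTIC", n_fib = 26)
  g <- generate_geometry(cfg, seed = 11)
  up <- rasterize_blobs(g$blobs$fib_upper, g$stack)
  lo <- rasterize_blobs(g$blobs$fib_lower, g$stack)
  thin <- derive_thin_fibrotic_mask(up, lo)
  ifd_mask <- 100 * (2 * sum(up) + 2 * sum(lo) + sum(thin)) /
    (5 * g$stack$nx * g$stack$ny)
  expect_equal(compute_ifd(g), ifd_mask)
})

test_that("accepted geometries satisfy labels partition and constraints", {
  cfg <- group_config("STOCHASTIC", n_fib = 26)
  g <- generate_geometry(cfg, seed = 5)
  st <- g$stack
  expect_true(all(g$labels %in% 1:3))
  expect_equal(length(g$labels), st$nx * st$ny * 9)
  # endo/epi all myocardial
  expect_true(all(g$labels[, , c(1, 9)] == 1L))
  # isolation layers contain only MYO / FIB_IL, fibrotic layers MYO / FIB_FL
  expect_true(all(g$labels[, , c(2, 8)] %in% c(1L, 3L)))
  expect_true(all(g$labels[, , 3:7] %in% c(1L, 2L)))
  # thin layer is the intersection of the thick-layer masks
  expect_identical(g$labels[, , 5] == 2L,
                   (g$labels[, , 3] == 2L) & (g$labels[, , 6] == 2L))
  # projection-constraint audit by mask oracle
  for (side in list(c(2, 3), c(8, 6))) {
    myo <- g$labels[, , side[1]] == 1L
    fib <- g$labels[, , side[2]] == 2L
    expect_equal(sum(myo & fib), 0)
  }
  # equal blob counts per paired layer
  expect_equal(nrow(g$blobs$myo_upper), nrow(g$blobs$myo_lower))
  expect_equal(nrow(g$blobs$fib_upper), nrow(g$blobs$fib_lower))
  # realized IFD within the configured window; EDD within [0, 100]
  expect_gte(g$ifd, cfg$ifd_window[1])
  expect_lte(g$ifd, cfg$ifd_window[2])
  expect_gte(g$edd, 0)
  expect_lte(g$edd, 100)
})

test_that("geometry generation is a pure function of (config, seed)", {
  cfg <- group_config("STOCHASTIC", n_fib = 26)
  g1 <- generate_geometry(cfg, seed = 3)
  g2 <- generate_geometry(cfg, seed = 3)
  expect_identical(g1$labels, g2$labels)
  expect_identical(g1$blobs, g2$blobs)
})

test_that("EDD decreases with myocardial blob count on seed averages", {
  st <- build_layer_stack()
  counts <- c(5, 9, 13, 17)
  mean_edd <- vapply(counts, function(n) {
    vals <- vapply(1:3, function(s) {
      set.seed(s)
      blobs <- sample_blob_set(st, n, 2.5, "MYOCARDIAL")
      100 * mean(!rasterize_blobs(blobs, st))
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_edd) < 0))
})

test_that("fibrotic coverage grows with blob count (balance policy fixed)", {
  st <- build_layer_stack()
  counts <- c(26, 34, 42, 50)
  mean_cov <- vapply(counts, function(n) {
    vals <- vapply(1:3, function(s) {
      set.seed(s)
      mean(rasterize_blobs(sample_blob_set(st, n, 2.6, "FIBROTIC"), st))
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_cov) > 0))
})

test_that("dissociation-controlled replicates share the myocardial layout", {
  reps <- generate_controlled_replicates("DISSOCIATION_CONTROLLED",
                                         n_myo = 13, n_fib = 30,
                                         n_replicates = 3, seed = 2)
  expect_identical(reps[[1]]$blobs$myo_upper, reps[[2]]$blobs$myo_upper)
  expect_identical(reps[[1]]$blobs$myo_lower, reps[[3]]$blobs$myo_lower)
  expect_identical(reps[[1]]$labels[, , 2], reps[[2]]$labels[, , 2])
  # fibrotic layouts differ
  expect_false(identical(reps[[1]]$blobs$fib_upper, reps[[2]]$blobs$fib_upper))
  edd <- vapply(reps, compute_edd, 0)
  expect_true(all(abs(edd - edd[1]) < 1e-12))
})

test_that("interrelated series follows the printed pairs with a common core", {
  cfg <- group_config("INTERRELATED", n_myo = 5, n_fib = 55)
  base <- generate_geometry(cfg, seed = 7)
  ser <- derive_interrelated_series(base, seed = 7)
  expect_length(ser, 13)
  pairs <- fibroslab:::INTERRELATED_PAIRS
  for (i in seq_along(ser)) {
    expect_equal(nrow(ser[[i]]$blobs$myo_upper), pairs$n_myo[i])
    expect_equal(nrow(ser[[i]]$blobs$fib_upper), pairs$n_fib[i])
    w <- ifd_window("INTERRELATED", pairs$n_fib[i])
    expect_gte(ser[[i]]$ifd, w[1])
    expect_lte(ser[[i]]$ifd, w[2])
  }
  # the first member's myocardial blobs persist through the whole series
  first_myo <- ser[[1]]$blobs$myo_upper[, c("x", "y")]
  last_myo <- ser[[13]]$blobs$myo_upper[seq_len(5), c("x", "y")]
  expect_equal(first_myo, last_myo)
  # a common fibrotic core (never-removed lowest-indexed blobs) is shared
  core <- min(pairs$n_fib)
  core_xy <- lapply(ser, function(g) g$blobs$fib_upper[seq_len(core), c("x", "y")])
  shared <- vapply(core_xy, function(m) {
    sum(paste(m$x, m$y) %in% paste(core_xy[[1]]$x, core_xy[[1]]$y))
  }, 0)
  expect_true(all(shared >= 1))
})

test_that("ifd_window interpolates and rejects out-of-range counts", {
  w26 <- ifd_window("STOCHASTIC", 26)
  expect_equal(unname(w26), c(21.5, 22.5))
  w28 <- ifd_window("STOCHASTIC", 28)
  expect_true(w28[1] > w26[1] && w28[2] < ifd_window("STOCHASTIC", 30)[2])
  expect_error(ifd_window("STOCHASTIC", 60), "outside")
})
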