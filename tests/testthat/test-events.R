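# constructed toy movies -----------------------------------------------------

# plane wave sweeping +x at 1 column/frame on an nx x ny sheet
plane_wave_movie <- function(nx = 20, ny = 20, nT = 25, rest = -74, peak = 10) {
  arr <- array(rest, dim = c(nx, ny, nT))
  for (t in 2:nT) {
    front <- min(t - 1, nx)
    arr[1:front, , t] <- peak
  }
  arr
}

test_that("a plane wave yields one parented component per frame", {
  mv <- plane_wave_movie()
  comps <- detect_activation_components(mv)
  for (t in 3:20) {
    expect_length(comps[[t]], 1)
    expect_equal(comps[[t]][[1]]$n_parents, 1L)
  }
  # frame 2 opens the wave: parentless
  expect_equal(comps[[2]][[1]]$n_parents, 0L)
})

test_that("a quiescent sheet yields no components", {
  mv <- array(-74, dim = c(10, 10, 10))
  comps <- detect_activation_components(mv)
  expect_true(all(vapply(comps, length, 1L) == 0))
})

test_that("two simultaneous distant onsets give two parentless components", {
  mv <- array(-74, dim = c(30, 30, 6))
  mv[2:4, 2:4, 3] <- 10
  mv[25:27, 25:27, 3] <- 10
  comps <- detect_activation_components(mv)
  expect_length(comps[[3]], 2)
  expect_true(all(vapply(comps[[3]], `[[`, 0L, "n_parents") == 0L))
})

test_that("breakthroughs are classified veritable versus annihilated", {
  # growing pulse that merges with a sheet wave: veritable
  nx <- 30; ny <- 30; nT <- 30
  mv <- array(-74, dim = c(nx, ny, nT))
  for (t in 5:nT) mv[(nx - min(t - 5, 12)):nx, , t] <- 10  # sheet wave
  mv[5:6, 5:6, 8] <- 10
  for (t in 9:nT) {
    gr <- min(t - 7, 10)
    mv[max(1, 5 - gr):min(nx, 6 + gr), max(1, 5 - gr):min(ny, 6 + gr), t] <- 10
  }
  ev <- detect_breakthroughs(mv, geometry = NULL)
  expect_gte(nrow(ev), 1)
  expect_true(any(ev$veritable))

  # small pulse dying within 3 frames: candidate but not veritable
  mv2 <- array(-74, dim = c(nx, ny, nT))
  mv2[10:11, 10:11, 5] <- 10
  mv2[10:11, 10:11, 6] <- 10
  ev2 <- detect_breakthroughs(mv2, geometry = NULL)
  expect_equal(nrow(ev2), 1)
  expect_false(any(ev2$veritable))
  expect_lt(ev2$extent[1], 25)
})

test_that("parentless components off the patch projections are not events", {
  # hand geometry: one central patch; a pulse far from it must be ignored
  labels <- array(1L, dim = c(20, 20, 9))
  labels[, , c(2, 8)] <- 3L
  labels[9:12, 9:12, c(2, 8)] <- 1L
  st <- build_layer_stack(c(8, 8, 3.6), 0.4)
  geom <- structure(list(stack = st, labels = labels),
                    class = "fs_slab_geometry")
  mv <- array(-74, dim = c(20, 20, 15))
  mv[2:3, 17:19, 6:9] <- 10  # far corner, off the patch
  ev <- detect_breakthroughs(mv, geom, "endo")
  expect_equal(nrow(ev), 0)
  # the same pulse over the patch is an event seeded by that patch
  mv2 <- array(-74, dim = c(20, 20, 15))
  mv2[9:12, 9:12, 6:15] <- 10
  ev2 <- detect_breakthroughs(mv2, geom, "endo")
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$seed_patch, 1L)
})

test_that("breakthrough location maps count onsets with window filters", {
  ev <- data.frame(onset_frame = c(100, 200, 4000), x = c(1, 1, 5),
                   y = c(1, 1, 5), seed_patch = 1L,
                   veritable = c(TRUE, TRUE, TRUE), extent = 30L,
                   survival_ms = 10L)
  m <- breakthrough_location_map(ev, c(20, 20))
  expect_equal(sum(m), 3)
  expect_equal(m[3, 3], 2)  # x = y = 1 mm -> element (3, 3) at 0.4 mm pitch
  m3s <- breakthrough_location_map(ev, c(20, 20), window_s = c(0, 3))
  expect_equal(sum(m3s), 2)
  expect_equal(sum(breakthrough_location_map(ev[0, ], c(20, 20))), 0)
})

test_that("a constructed transmural loop is detected as intramural re-entry", {
  # geometry: two patches, one per isolation layer, at distinct corners
  labels <- array(1L, dim = c(20, 20, 9))
  labels[, , c(2, 8)] <- 3L
  labels[4:7, 4:7, 2] <- 1L     # endo-side patch
  labels[14:17, 14:17, 8] <- 1L # epi-side patch
  st <- build_layer_stack(c(8, 8, 3.6), 0.4)
  geom <- structure(list(stack = st, labels = labels),
                    class = "fs_slab_geometry")
  period <- 40
  nT <- 200
  mv <- array(-74, dim = c(20, 20, 9, nT))
  for (cycle in 0:3) {
    t0 <- 10 + cycle * period
    # endo breakthrough over the endo patch, growing
    for (dt in 0:8) {
      g <- min(dt, 6)
      mv[max(1, 4 - g):min(20, 7 + g), max(1, 4 - g):min(20, 7 + g), 1,
         t0 + dt] <- 10
    }
    # transmural wall path active (descends through the connection wall)
    for (dt in 0:12) {
      mv[4:17, 4:17, 2:8, t0 + 4 + dt] <- 10
    }
    # epi breakthrough over the epi patch, delayed by half a period
    for (dt in 0:8) {
      g <- min(dt, 6)
      mv[max(1, 14 - g):min(20, 17 + g), max(1, 14 - g):min(20, 17 + g), 9,
         t0 + 18 + dt] <- 10
    }
  }
  movie <- matrix(mv, nrow = 20 * 20 * 9, ncol = nT)
  res <- structure(list(movie = movie, times = (seq_len(nT) - 1) / 1000,
                        dims = c(20, 20, 9), element_size = 0.4,
                        duration_s = nT / 1000, termination = "max_time",
                        geometry = geom),
                   class = "fs_simulation_result")
  rec <- detect_intramural_reentry(res)
  expect_gte(nrow(rec), 1)
  expect_true(any(rec$circuit_confirmed))
  expect_equal(rec$period_ms[1], period, tolerance = 0.1 * period)

  # counterexample: periodic endo breakthroughs with a quiescent wall
  mv2 <- mv
  mv2[, , 3:7, ] <- -74
  res2 <- res
  res2$movie <- matrix(mv2, nrow = 20 * 20 * 9, ncol = nT)
  rec2 <- detect_intramural_reentry(res2)
  expect_true(nrow(rec2) == 0 || !any(rec2$circuit_confirmed))

  # quiescent movie: empty
  res3 <- res
  res3$movie <- matrix(-74, nrow = 20 * 20 * 9, ncol = nT)
  expect_equal(nrow(detect_intramural_reentry(res3)), 0)
})
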