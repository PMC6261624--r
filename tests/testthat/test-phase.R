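# synthetic helpers ----------------------------------------------------------

# archimedean k-armed spiral phase field on an nx x ny grid (element centers)
spiral_phase <- function(nx, ny, x0, y0, h = 0.4, chirality = 1, k = 1) {
  cx <- (seq_len(nx) - 0.5) * h
  cy <- (seq_len(ny) - 0.5) * h
  outer(cx, cy, function(x, y) {
    fibroslab:::wrap_phase(chirality * k * atan2(y - y0, x - x0))
  })
}

test_that("phase definition follows the delayed-coordinate arctangent", {
  # V(t) - Vmean = 1, V(t+tau) - Vmean = 0 -> theta = 0
  # build a 1-element movie realizing those samples at t = 1
  tau <- 30
  v <- rep(0, 40)
  v[1] <- 1          # V(1) = Vmean + 1
  v[1 + tau] <- 0    # V(31) = Vmean
  sheet <- array(rep(v, each = 1), dim = c(1, 1, 40))
  vmean <- mean(v)
  ph <- compute_phase(sheet, tau)
  expect_equal(ph$theta[1, 1, 1], atan2(v[1 + tau] - vmean, v[1] - vmean))

  # pure quadrature pair: sin leads by pi/2 over tau = quarter period
  f <- 1000 / (4 * 30)  # period = 4 tau at 1 kHz
  t <- 0:499
  v <- sin(2 * pi * f * t / 1000)
  sheet <- array(v, dim = c(1, 1, length(v)))
  ph <- compute_phase(sheet, 30)
  th <- ph$theta[1, 1, ]
  # phase advances 2 pi per period: unwrapped increments sum to ~2 pi f T
  inc <- fibroslab:::wrap_phase(diff(th))
  expect_equal(abs(sum(inc)) / (2 * pi), f * (length(th) - 1) / 1000,
               tolerance = 0.02)
  expect_true(all(th > -pi & th <= pi))
})

test_that("undefined phases are flagged when both arguments vanish", {
  sheet <- array(5, dim = c(2, 2, 50))  # flat signal, V = Vmean always
  ph <- compute_phase(sheet, 30)
  expect_true(all(is.na(ph$theta)))
  expect_equal(nrow(detect_phase_singularities(ph$theta[, , 1])), 0)
  expect_error(compute_phase(array(0, c(1, 1, 10)), 30), "tau")
})

test_that("detector recovers the analytic spiral singularity", {
  for (ch in c(1, -1)) {
    th <- spiral_phase(40, 40, x0 = 8.1, y0 = 8.1, chirality = ch)
    ps <- detect_phase_singularities(th, 0.4)
    expect_equal(nrow(ps), 1)
    expect_lt(abs(ps$x - 8.1), 0.4)  # within one element
    expect_lt(abs(ps$y - 8.1), 0.4)
    expect_equal(ps$chirality, ch)
  }
  # uniform phase: no singularities
  expect_equal(nrow(detect_phase_singularities(matrix(1.2, 30, 30))), 0)
  # mirroring the field flips the chirality but not the position
  th <- spiral_phase(40, 40, 8.1, 8.1, chirality = 1)
  ps <- detect_phase_singularities(th, 0.4)
  ps_m <- detect_phase_singularities(-th, 0.4)
  expect_equal(ps_m$x, ps$x)
  expect_equal(ps_m$chirality, -ps$chirality)
})

test_that("brute-force loop integral agrees with the detector", {
  th <- spiral_phase(25, 25, 5.3, 4.9)
  ps <- detect_phase_singularities(th, 0.4)
  wrap <- fibroslab:::wrap_phase
  oracle <- NULL
  for (i in 1:24) {
    for (j in 1:24) {
      s <- wrap(th[i + 1, j] - th[i, j]) + wrap(th[i + 1, j + 1] - th[i + 1, j]) +
        wrap(th[i, j + 1] - th[i + 1, j + 1]) + wrap(th[i, j] - th[i, j + 1])
      if (abs(s) > pi) oracle <- rbind(oracle, c(i * 0.4, j * 0.4, sign(s)))
    }
  }
  expect_equal(nrow(ps), nrow(oracle))
  expect_equal(ps$x, oracle[, 1])
  expect_equal(ps$y, oracle[, 2])
})

test_that("chirality sum matches the boundary winding (index theorem)", {
  wrap <- fibroslab:::wrap_phase
  boundary_winding <- function(th) {
    nx <- nrow(th); ny <- ncol(th)
    path <- rbind(cbind(1:nx, 1), cbind(nx, 1:ny), cbind(nx:1, ny), cbind(1, ny:1))
    vals <- th[path]
    sum(wrap(diff(c(vals, vals[1])))) / (2 * pi)
  }
  fields <- list(
    spiral_phase(30, 30, 6.3, 5.7, chirality = 1),
    spiral_phase(30, 30, 6.3, 5.7, chirality = -1),
    spiral_phase(30, 30, 5.9, 6.1, k = 1) )
  set.seed(4)
  for (th in fields) {
    ps <- detect_phase_singularities(th, 0.4)
    expect_equal(sum(ps$chirality), round(boundary_winding(th)))
  }
})

test_that("track linkage obeys the 1 mm / 1 ms gate", {
  fr <- function(...) {
    m <- rbind(...)
    data.frame(x = m[, 1], y = m[, 2], chirality = 1L)
  }
  empty <- data.frame(x = numeric(0), y = numeric(0), chirality = integer(0))
  # 0.5 mm step: one track of two frames
  tr <- track_singularities(list(fr(c(10, 10)), fr(c(10.5, 10))))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$birth, 1)
  expect_equal(tr$death, 2)
  # 2 mm jump: gate exceeded, two tracks
  tr <- track_singularities(list(fr(c(10, 10)), fr(c(12, 10))))
  expect_equal(nrow(tr), 2)
  # two convergent singularities, one successor: nearest wins, other closes
  tr <- track_singularities(list(fr(c(10, 10), c(10.9, 10)), fr(c(10.8, 10))))
  expect_equal(nrow(tr), 2)
  linked <- tr[tr$death == 2, ]
  expect_equal(linked$x[[1]][1], 10.9)  # the nearer parent got the successor
  # exact tie: the older (lower-id) track wins
  tr <- track_singularities(list(fr(c(9.5, 10), c(10.5, 10)), fr(c(10, 10))))
  expect_equal(tr$death[1], 2)
  expect_equal(tr$death[2], 1)
  # a vanishing singularity closes its track
  tr <- track_singularities(list(fr(c(5, 5)), empty, fr(c(5, 5))))
  expect_equal(nrow(tr), 2)
})

test_that("per-frame counts reconcile with track lifespans", {
  set.seed(2)
  # random walks with births and deaths
  frames <- list()
  pos <- matrix(runif(6, 5, 15), 3, 2)
  for (t in 1:30) {
    alive <- seq_len(nrow(pos))
    if (t > 10) alive <- alive[-1]
    frames[[t]] <- data.frame(x = pos[alive, 1], y = pos[alive, 2],
                              chirality = 1L)
    pos <- pos + matrix(runif(6, -0.3, 0.3), 3, 2)
  }
  tr <- track_singularities(frames)
  st <- ps_statistics(tr, duration_s = 0.03)
  counts <- st$count_series
  expect_gte(nrow(tr), max(counts))
  # sum of per-frame counts equals total frames covered by all tracks
  expect_equal(sum(counts), sum(tr$death - tr$birth + 1))
})

test_that("PS statistics arithmetic", {
  tr <- data.frame(id = 1:3, birth = c(1, 1, 101), death = c(101, 201, 401),
                   chirality = 1L)
  tr$lifespan_ms <- tr$death - tr$birth
  st <- ps_statistics(tr, duration_s = 5)
  expect_equal(st$mean_lifespan_ms, mean(c(100, 200, 300)))
  expect_equal(st$generation_rate_per_s, 3 / 5)
  # 50 tracks over 5 s -> 10 per second
  tr50 <- data.frame(id = 1:50, birth = 1:50, death = 2:51, chirality = 1L)
  tr50$lifespan_ms <- 1
  expect_equal(ps_statistics(tr50, 5)$generation_rate_per_s, 10)
  expect_error(ps_statistics(tr, 0), "positive")
})

test_that("stability classification uses the strict 10 s rule", {
  expect_equal(classify_stability(10.5), "STABLE")
  expect_equal(classify_stability(3.0), "NON_STABLE")
  expect_equal(classify_stability(10.0), "NON_STABLE")  # strictly more than
})
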