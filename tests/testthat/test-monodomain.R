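# helpers -------------------------------------------------------------------

no_stim_protocol <- function(dims_elem) {
  structure(list(stimuli = list(), dims = dims_elem + 1L),
            class = "fs_stim_protocol")
}

strip_cv <- function(sigma_myo, element_size = 0.4, n_long = 60,
                     max_time = 0.1) {
  labels <- array(1L, dim = c(n_long, 3L, 1L))
  cfg <- solver_config(max_time = max_time)
  prot <- s1s2_protocol(dim(labels), s2 = FALSE)
  r <- run_simulation(labels, prot, cfg,
                      sigma_mS_cm = c(MYO = sigma_myo, FIB_FL = 0.1, FIB_IL = 0),
                      element_size_mm = element_size)
  sh <- movie_sheet(r, 1)
  act <- function(i) {
    v <- sh[i, 2, ]
    w <- which(v > -40)
    if (length(w)) r$times[w[1]] else NA_real_
  }
  i1 <- round(n_long / 3); i2 <- round(2 * n_long / 3)
  (i2 - i1) * element_size / 1000 / (act(i2) - act(i1))
}

# operators ------------------------------------------------------------------

test_that("stiffness operator annihilates constants (zero-flux null space)", {
  labels <- array(1L, dim = c(5, 4, 3))
  ops <- assemble_operators(labels, 0.4)
  v <- rep(3.7, prod(ops$dims))
  expect_lt(max(abs(as.numeric(ops$K %*% v))), 1e-12)
  # the implicit system then maps a constant onto its mass scaling
  expect_equal(as.numeric(ops$A %*% v), ops$md * v, tolerance = 1e-12)
})

test_that("single-element stiffness equals the trilinear brick matrix", {
  labels <- array(1L, dim = c(1, 1, 1))
  cfg <- solver_config(beta = 250)
  ops <- assemble_operators(labels, 0.4, cfg)
  sig_h <- 0.5e-3 * 0.04  # sigma S/cm * h cm
  corners <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  Khat <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    nd <- sum(corners[i, ] != corners[j, ])
    Khat[i, j] <- c(1 / 3, 0, -1 / 12, -1 / 12)[nd + 1]
  }
  expect_equal(as.matrix(ops$K), sig_h * Khat, tolerance = 1e-12,
               ignore_attr = TRUE)
  # lumped mass: each of the 8 corner nodes carries beta*cm*h^3/8
  expect_equal(ops$mass, rep(250 * 1e-6 * 0.04^3 / 8, 8), tolerance = 1e-12)
})

test_that("zero conductivity yields an empty stiffness operator", {
  labels <- array(3L, dim = c(4, 4, 2))  # FIB_IL everywhere, sigma = 0
  ops <- assemble_operators(labels, 0.4)
  expect_equal(Matrix::nnzero(ops$K), 0)
  v <- rnorm(prod(ops$dims), -70, 10)
  x <- fibroslab:::cpp_cg_solve(ops$A@p, ops$A@i, ops$A@x, ops$md * v)
  expect_equal(as.numeric(x), v, tolerance = 1e-9)  # diffusion leaves V alone
})

test_that("stimulus currents appear only in their windows and footprints", {
  prot <- s1s2_protocol(c(10, 10, 3))
  expect_true(all(apply_stimulus(prot, 0.0005) == 0))
  s1 <- apply_stimulus(prot, 0.0015)
  on <- which(s1 != 0)
  expect_setequal(on, prot$stimuli[[1]]$elements)
  expect_true(all(s1[on] == prot$stimuli[[1]]$amplitude))
  s2 <- apply_stimulus(prot, prot$stimuli[[2]]$onset + 5e-4)
  expect_setequal(which(s2 != 0), prot$stimuli[[2]]$elements)
  # footprints live on the endocardial node plane only
  n_plane <- 11 * 11
  expect_true(all(prot$stimuli[[1]]$elements <= n_plane))
  expect_true(all(prot$stimuli[[2]]$elements <= n_plane))
})

test_that("implicit diffusion conserves capacitance-weighted voltage", {
  labels <- array(1L, dim = c(8, 8, 3))
  ops <- assemble_operators(labels, 0.4)
  set.seed(1)
  v <- rnorm(prod(ops$dims), -70, 20)
  x <- fibroslab:::cpp_cg_solve(ops$A@p, ops$A@i, ops$A@x, ops$md * v,
                                tol = 1e-10)
  expect_lt(abs(sum(ops$mass * x) - sum(ops$mass * v)) /
              abs(sum(ops$mass * v)), 1e-8)
  resid <- as.numeric(ops$A %*% x) - ops$md * v
  expect_lt(sqrt(sum(resid^2)) / sqrt(sum((ops$md * v)^2)), 1e-8)
})

test_that("uniform resting tissue stays at equilibrium", {
  labels <- array(1L, dim = c(6, 6, 3))
  cfg <- solver_config(max_time = 0.001)  # 100 steps
  # pure diffusion: exactly preserved
  r0 <- run_simulation(labels, no_stim_protocol(dim(labels)), cfg,
                       reaction_on = FALSE)
  expect_lt(max(abs(r0$movie[, ncol(r0$movie)] - r0$movie[, 1])), 1e-6)
  # with reaction: only the slow settling drift remains
  r1 <- run_simulation(labels, no_stim_protocol(dim(labels)), cfg)
  expect_lt(max(abs(r1$movie[, ncol(r1$movie)] - r1$movie[, 1])), 1e-3)
})

test_that("mirror-symmetric stimulus gives mirror-symmetric voltages", {
  labels <- array(1L, dim = c(16, 15, 1))
  cfg <- solver_config(max_time = 0.03)
  prot <- s1s2_protocol(dim(labels), s2 = FALSE)  # S1 line symmetric in y
  r <- run_simulation(labels, prot, cfg)
  sh <- movie_sheet(r, 1)
  flipped <- sh[, rev(seq_len(dim(sh)[2])), , drop = FALSE]
  expect_equal(sh, flipped, tolerance = 1e-6)
})

test_that("conduction velocity is physiological and decreases with sigma", {
  cv05 <- strip_cv(0.5)
  cv01 <- strip_cv(0.1, max_time = 0.3)  # slow tissue needs a longer window
  expect_gt(cv05, 0.3)
  expect_lt(cv05, 0.7)
  expect_lt(cv01, cv05)
})

test_that("halving the mesh size changes CV by less than 15%", {
  cv04 <- strip_cv(0.5, element_size = 0.4, n_long = 60)
  cv02 <- strip_cv(0.5, element_size = 0.2, n_long = 120)
  expect_lt(abs(cv02 - cv04) / cv04, 0.15)
})

test_that("fully fibrotic isolation layers block transmural conduction", {
  labels <- array(1L, dim = c(20, 20, 9))
  labels[, , c(2, 8)] <- 3L  # EDD = 100%
  cfg <- solver_config(max_time = 0.08)
  prot <- s1s2_protocol(dim(labels), s2 = FALSE)
  r <- run_simulation(labels, prot, cfg)
  epi <- movie_sheet(r, "epi")
  endo <- movie_sheet(r, "endo")
  expect_gt(max(endo), -40)                 # endocardium activates
  expect_lt(max(epi) - max(epi[, , 1]), 1)  # epicardium never leaves rest
})

test_that("a single isolation patch conducts endo to epi over its footprint", {
  labels <- array(1L, dim = c(20, 20, 9))
  labels[, , c(2, 8)] <- 3L
  # one myocardial patch (2.5 mm radius disc) in both isolation layers
  ctr <- expand.grid(i = 1:20, j = 1:20)
  inside <- with(ctr, ((i - 0.5) * 0.4 - 4)^2 + ((j - 0.5) * 0.4 - 4)^2 <= 2.5^2)
  patch <- matrix(FALSE, 20, 20)
  patch[cbind(ctr$i[inside], ctr$j[inside])] <- TRUE
  for (sl in c(2, 8)) {
    m <- labels[, , sl]
    m[patch] <- 1L
    labels[, , sl] <- m
  }
  # representative intramural fibrosis in the connection wall (the study's
  # slabs are never fibrosis-free); the transmural route stays clear per
  # the projection constraint
  set.seed(5)
  for (sl in 3:7) {
    m <- labels[, , sl]
    fib <- matrix(runif(400) < 0.3, 20, 20)
    if (sl %in% c(3, 4, 6, 7)) fib <- fib & !patch
    m[fib & m == 1L] <- 2L
    labels[, , sl] <- m
  }
  cfg <- solver_config(max_time = 0.12)
  prot <- s1s2_protocol(dim(labels), s2 = FALSE)
  r <- run_simulation(labels, prot, cfg)
  endo <- movie_sheet(r, "endo")
  epi <- movie_sheet(r, "epi")
  act_time <- function(sheet) {
    nt <- dim(sheet)[3]
    at <- matrix(NA_real_, dim(sheet)[1], dim(sheet)[2])
    for (t in seq_len(nt)) {
      newly <- sheet[, , t] > -40 & is.na(at)
      at[newly] <- t
    }
    at
  }
  at_endo <- act_time(endo)
  at_epi <- act_time(epi)
  expect_true(any(!is.na(at_epi)))
  # epicardial activation is strictly later than endocardial onset
  expect_gt(min(at_epi, na.rm = TRUE), min(at_endo, na.rm = TRUE))
  # earliest epicardial activation lies over the patch footprint
  first <- which(at_epi == min(at_epi, na.rm = TRUE), arr.ind = TRUE)
  node_patch <- element_mask_to_nodes(patch)
  near_patch <- fibroslab:::dilate8(node_patch) | node_patch
  expect_true(all(near_patch[first]))
})

test_that("simulations are deterministic", {
  labels <- array(1L, dim = c(10, 10, 1))
  cfg <- solver_config(max_time = 0.02)
  prot <- s1s2_protocol(dim(labels), s2 = FALSE)
  r1 <- run_simulation(labels, prot, cfg)
  r2 <- run_simulation(labels, prot, cfg)
  expect_identical(r1$movie, r2$movie)
})

test_that("advance_time_step composes like a single longer run", {
  labels <- array(1L, dim = c(8, 8, 1))
  prot <- s1s2_protocol(dim(labels), s2 = FALSE)
  cfg <- solver_config(max_time = 10 * 1e-5)
  r <- run_simulation(labels, prot, cfg, return_states = TRUE)
  st <- steady_state_init(cell_params(3))
  sf <- steady_state_init(cell_params(45))
  full0 <- matrix(rep(st, prod(dim(labels) + 1L)), nrow = 32)
  s1 <- advance_time_step(full0, labels, prot, solver_config(), t0 = 0,
                          n_steps = 5)
  s2 <- advance_time_step(s1, labels, prot, solver_config(), t0 = 5e-5,
                          n_steps = 5)
  expect_equal(s2[1, ], r$states[1, ], tolerance = 1e-9)
  # zero-derivative sanity: with no stimulus pending and a uniform settled
  # state, a step barely moves the voltage
  prot0 <- structure(list(stimuli = list(), dims = dim(labels) + 1L),
                     class = "fs_stim_protocol")
  s3 <- advance_time_step(full0, labels, prot0, solver_config(), n_steps = 1)
  expect_lt(max(abs(s3[1, ] - full0[1, ])), 1e-3)
})
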