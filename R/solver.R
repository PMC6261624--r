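#' Per-element conductivity from tissue classes
#'
#' Isotropic monodomain conductivities: 0.5 mS/cm for myocardium, 0.1 mS/cm
#' for fibrotic tissue in fibrotic layers, and 0 for fibrotic tissue in
#' isolation layers (internal zero-flux barriers).
#'
#' @param labels integer array of tissue classes (1 MYO, 2 FIB_FL, 3 FIB_IL),
#'   or an `fs_slab_geometry`.
#' @param sigma_mS_cm conductivity by class, mS/cm.
#' @return numeric array of per-element conductivities (mS/cm).
#' @export
conductivity_field <- function(labels,
                               sigma_mS_cm = c(MYO = 0.5, FIB_FL = 0.1,
                                               FIB_IL = 0)) {
  if (inherits(labels, "fs_slab_geometry")) labels <- labels$labels
  stopifnot(all(labels %in% 1:3))
  array(sigma_mS_cm[as.integer(labels)], dim = dim(labels))
}

#' Solver configuration
#'
#' @param dt reaction/diffusion time step in seconds (10 us).
#' @param cg_tol conjugate-gradient convergence tolerance (relative
#'   residual).
#' @param output_rate_hz sampling rate of the stored voltage movie (Hz);
#'   `dt` must divide the output interval.
#' @param max_time maximal simulated time (s).
#' @param beta membrane surface-to-volume ratio (1/cm).  The default is
#'   calibrated so a plane wave in myocardial tissue (0.5 mS/cm) conducts
#'   at ~0.5 m/s on the 0.4 mm mesh.
#' @param cm_spec specific membrane capacitance used in the diffusion
#'   scaling (uF/cm^2).
#' @param stability_threshold_s activity duration above which a simulation
#'   is classified stable (10 s at paper scale).
#' @param ext_threshold_mV,ext_window_ms extinction detector: the run stops
#'   once the maximal tissue voltage stays below the threshold for the
#'   whole window after all stimuli.
#' @param cg_maxit iteration cap for each CG solve.
#' @return list of class `fs_solver_config`.
#' @export
solver_config <- function(dt = 1e-5, cg_tol = 1e-8, output_rate_hz = 1000,
                          max_time = 1, beta = 350, cm_spec = 1,
                          stability_threshold_s = 10,
                          ext_threshold_mV = -60, ext_window_ms = 20,
                          cg_maxit = 10000L) {
  sample_every <- 1 / (output_rate_hz * dt)
  if (abs(sample_every - round(sample_every)) > 1e-9) {
    stop("dt must divide the output interval 1/output_rate_hz", call. = FALSE)
  }
  structure(list(dt = dt, cg_tol = cg_tol, output_rate_hz = output_rate_hz,
                 sample_every = as.integer(round(sample_every)),
                 max_time = max_time, beta = beta, cm_spec = cm_spec,
                 stability_threshold_s = stability_threshold_s,
                 ext_threshold_mV = ext_threshold_mV,
                 ext_window_ms = ext_window_ms,
                 cg_maxit = as.integer(cg_maxit)),
            class = "fs_solver_config")
}

# Dimensionless local stiffness of the trilinear brick (unit conductivity,
# multiplied by sigma * h at assembly).  Node order: binary (x, y, z)
# offsets 000, 100, 010, 110, 001, 101, 011, 111.  Entries: diagonal 1/3,
# edge neighbors 0, face and body diagonals -1/12.
trilinear_brick_stiffness <- function() {
  corners <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  K <- matrix(0, 8, 8)
  for (i in 1:8) {
    for (j in 1:8) {
      ndiff <- sum(corners[i, ] != corners[j, ])
      K[i, j] <- c(1 / 3, 0, -1 / 12, -1 / 12)[ndiff + 1]
    }
  }
  K
}

#' Assemble the discrete diffusion operators
#'
#' Trilinear hexahedral finite-element discretization of
#' `div(sigma grad V)` with natural zero-flux boundaries: membrane voltage
#' unknowns live on the element-corner nodes of the `(nx+1) x (ny+1) x
#' (nz+1)` node grid, each element contributes its local trilinear brick
#' stiffness scaled by its conductivity, and the mass matrix is lumped
#' (each element spreads `beta * cm * h^3` over its 8 nodes).
#' Zero-conductivity elements contribute no stiffness, so a fully fibrotic
#' isolation layer is an internal zero-flux barrier while a myocardial
#' patch in it couples the two sides.
#'
#' @param labels tissue class array or `fs_slab_geometry`.
#' @param element_size_mm element edge length (mm).
#' @param config an `fs_solver_config` (supplies `beta`, `cm_spec`, `dt`).
#' @param sigma_mS_cm conductivity by class passed to [conductivity_field()].
#' @return list with sparse stiffness `K` (Siemens), system matrix
#'   `A = diag(mass/dt) + K` for the implicit diffusion sub-step, vectors
#'   `md` (nodal capacitance / dt, F/s) and `mass` (nodal capacitance, F),
#'   `dims` (node grid), `dims_elem` (element grid).
#' @export
assemble_operators <- function(labels, element_size_mm = 0.4,
                               config = solver_config(),
                               sigma_mS_cm = c(MYO = 0.5, FIB_FL = 0.1,
                                               FIB_IL = 0)) {
  if (inherits(labels, "fs_slab_geometry")) {
    element_size_mm <- labels$stack$element_size
    labels <- labels$labels
  }
  dims_e <- dim(labels)
  if (is.null(dims_e)) dims_e <- c(length(labels), 1L, 1L)
  if (length(dims_e) == 2) dims_e <- c(dims_e, 1L)
  sig <- as.numeric(conductivity_field(array(labels, dim = dims_e),
                                       sigma_mS_cm))
  nxe <- dims_e[1]; nye <- dims_e[2]; nze <- dims_e[3]
  dims_n <- dims_e + 1L
  Nn <- prod(dims_n)
  h_cm <- element_size_mm / 10

  # element origin nodes (flat index into the node grid)
  eidx <- seq_len(prod(dims_e))
  ei <- ((eidx - 1L) %% nxe) + 1L
  ej <- (((eidx - 1L) %/% nxe) %% nye) + 1L
  ek <- ((eidx - 1L) %/% (nxe * nye)) + 1L
  node_of <- function(a, b, cc) {
    (ei + a) + (ej + b - 1L) * dims_n[1] +
      (ek + cc - 1L) * dims_n[1] * dims_n[2]
  }
  corners <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  Khat <- trilinear_brick_stiffness()

  live <- sig > 0
  scale <- sig[live] * 1e-3 * h_cm  # sigma S/cm * h cm -> S
  ti <- list(); tj <- list(); tx <- list(); n <- 0L
  for (a in 1:8) {
    na <- node_of(corners[a, 1], corners[a, 2], corners[a, 3])[live]
    for (b in 1:8) {
      if (Khat[a, b] == 0) next
      nb <- node_of(corners[b, 1], corners[b, 2], corners[b, 3])[live]
      n <- n + 1L
      ti[[n]] <- na; tj[[n]] <- nb; tx[[n]] <- scale * Khat[a, b]
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(Nn, Nn))
  K <- methods::as(methods::as(K, "generalMatrix"), "CsparseMatrix")

  # lumped nodal capacitance: every element (conducting or not) carries
  # membrane; it spreads beta*cm*h^3 over its 8 corner nodes
  cap_e <- config$beta * config$cm_spec * 1e-6 * h_cm^3 / 8  # F per corner
  mass <- numeric(Nn)
  for (a in 1:8) {
    nd <- node_of(corners[a, 1], corners[a, 2], corners[a, 3])
    tab <- tabulate(nd, nbins = Nn)
    mass <- mass + cap_e * tab
  }
  md <- mass / config$dt
  A <- Matrix::Diagonal(Nn, md) + K
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  list(K = K, A = A, md = md, mass = mass, dims = dims_n, dims_elem = dims_e)
}

# Tissue class per node from the adjacent elements: majority vote over the
# (up to 8) touching elements, ties broken toward the more conducting class
# (MYO > FIB_FL > FIB_IL).
node_labels <- function(labels) {
  dims_e <- dim(labels)
  dims_n <- dims_e + 1L
  counts <- array(0L, dim = c(dims_n, 3))
  pad <- array(0L, dim = dims_n)
  for (cls in 1:3) {
    m <- array(0L, dim = dims_n)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      sl <- pad
      sl[(1:dims_e[1]) + a, (1:dims_e[2]) + b, (1:dims_e[3]) + cc] <-
        (labels == cls)
      m <- m + sl
    }
    counts[, , , cls] <- m
  }
  # which.max picks the first maximum: class order already encodes the
  # MYO > FIB_FL > FIB_IL tie-break
  out <- apply(counts, 1:3, which.max)
  array(as.integer(out), dim = dims_n)
}

#' S1-S2 stimulation protocol on the endocardium
#'
#' The conditioning stimulus S1 is a one-node-wide line along the full left
#' edge of the endocardial surface at t = 1 ms; the premature stimulus S2
#' covers the lower-left quadrant of the endocardial surface.  Both act
#' only on the endocardium.  The reference protocol places S2 at 280 ms;
#' the packaged default is the measured center of the vulnerable window of
#' the default parameter set (235 ms), since wavebreak timing depends on
#' coupling parameters the reference leaves open.
#'
#' @param dims element-grid dimensions `c(nx, ny, nz)`; stimuli address the
#'   corresponding node grid and the endocardial surface is node plane 1.
#' @param s1_time,s2_time stimulus onsets (s).
#' @param duration stimulus duration (s).
#' @param amplitude stimulus current per node (pA, negative = depolarizing);
#'   default is twice the calibrated diastolic threshold of the coupled
#'   tissue.
#' @param s2 include the S2 stimulus (set `FALSE` for a plane-wave run).
#' @return list of class `fs_stim_protocol`; each stimulus has `elements`
#'   (1-based flat node indices), `onset`, `duration`, `amplitude`; `dims`
#'   is the node grid.
#' @export
s1s2_protocol <- function(dims, s1_time = 0.001, s2_time = 0.235,
                          duration = 0.002, amplitude = -11000, s2 = TRUE) {
  dims_n <- dims + 1L
  nx <- dims_n[1]; ny <- dims_n[2]
  sheet <- function(i_keep, j_keep) {
    ij <- expand.grid(i = i_keep, j = j_keep)
    as.integer(ij$i + (ij$j - 1L) * nx)  # node plane 1 offset is zero
  }
  stims <- list(list(name = "S1", elements = sheet(1L, seq_len(ny)),
                     onset = s1_time, duration = duration,
                     amplitude = amplitude))
  if (s2) {
    stims <- c(stims, list(list(name = "S2",
                                elements = sheet(seq_len(nx %/% 2),
                                                 seq_len(ny %/% 2)),
                                onset = s2_time, duration = duration,
                                amplitude = amplitude)))
  }
  structure(list(stimuli = stims, dims = dims_n), class = "fs_stim_protocol")
}

#' Per-node stimulus current at a time point
#'
#' @param protocol an `fs_stim_protocol`.
#' @param t time (s).
#' @return numeric vector over all nodes (pA), nonzero only inside active
#'   stimulus footprints.
#' @export
apply_stimulus <- function(protocol, t) {
  out <- numeric(prod(protocol$dims))
  for (s in protocol$stimuli) {
    if (t >= s$onset && t < s$onset + s$duration) {
      out[s$elements] <- out[s$elements] + s$amplitude
    }
  }
  out
}

#' Run a monodomain tissue simulation
#'
#' Integrates the coupled reaction-diffusion system from the settled
#' resting state: per-node coupled-unit reaction by forward Euler, then an
#' implicit diffusion sub-step `(M/dt + K) V+ = (M/dt) V` solved by
#' conjugate gradients to the configured tolerance.  The voltage movie is
#' sampled at the configured output rate (1 kHz default) on the node grid.
#' The run stops early when activity is extinct (all voltages below the
#' extinction threshold for the whole extinction window once no stimulus
#' is pending).
#'
#' @param geometry an `fs_slab_geometry`, or a raw integer label array.
#' @param protocol an `fs_stim_protocol` (see [s1s2_protocol()]).
#' @param config an `fs_solver_config`.
#' @param params_myo,params_fib cell parameters for myocardial (numf = 3)
#'   and fibrotic (numf = 45) units.
#' @param sigma_mS_cm conductivity by tissue class (mS/cm).
#' @param reaction_on disable to integrate pure diffusion (testing).
#' @param element_size_mm element edge length when `geometry` is a raw
#'   label array (ignored for `fs_slab_geometry` input).
#' @param return_states keep the full final state matrix.
#' @param init_states optional 32 x 3 matrix of per-class initial unit
#'   states; defaults to the cached settled states.
#' @return `fs_simulation_result`: `movie` (nodes x frames, mV), `times`
#'   (s), `dims` (node grid), `duration_s`, `termination`, `protocol`,
#'   `config`.
#' @export
run_simulation <- function(geometry, protocol, config = solver_config(),
                           params_myo = cell_params(numf = 3),
                           params_fib = cell_params(numf = 45),
                           sigma_mS_cm = c(MYO = 0.5, FIB_FL = 0.1,
                                           FIB_IL = 0),
                           reaction_on = TRUE, element_size_mm = 0.4,
                           return_states = FALSE, init_states = NULL) {
  labels <- if (inherits(geometry, "fs_slab_geometry")) geometry$labels else geometry
  element_size <- if (inherits(geometry, "fs_slab_geometry"))
    geometry$stack$element_size else element_size_mm
  if (is.null(dim(labels))) dim(labels) <- c(length(labels), 1L, 1L)
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1L)
  ops <- assemble_operators(labels, element_size, config, sigma_mS_cm)
  nlab <- node_labels(labels)
  if (!identical(dim(nlab), as.integer(ops$dims))) {
    stop("internal: node label grid mismatch", call. = FALSE)
  }
  if (!identical(as.integer(protocol$dims), as.integer(ops$dims))) {
    stop("protocol node grid ", paste(protocol$dims, collapse = "x"),
         " does not match the mesh node grid ",
         paste(ops$dims, collapse = "x"), call. = FALSE)
  }
  if (is.null(init_states)) {
    st_myo <- steady_state_init(params_myo)
    st_fib <- steady_state_init(params_fib)
    init_states <- cbind(st_myo, st_fib, st_fib)
  }
  stim <- protocol$stimuli
  stim_elem <- unlist(lapply(stim, function(s) s$elements - 1L))
  if (is.null(stim_elem)) stim_elem <- integer(0)
  stim_ptr <- c(0L, cumsum(vapply(stim, function(s) length(s$elements), 1L)))
  n_steps <- as.integer(round(config$max_time / config$dt))
  res <- cpp_simulate(as.integer(nlab), ops$A@p, ops$A@i, ops$A@x, ops$md,
                      init_states,
                      numf_by_class = c(params_myo$numf, params_fib$numf,
                                        params_fib$numf),
                      ggap = params_myo$ggap, cm_myo = params_myo$cm_myo,
                      cm_fb = params_myo$cm_fb,
                      stim_elem = as.integer(stim_elem),
                      stim_ptr = as.integer(stim_ptr),
                      stim_onset = vapply(stim, `[[`, 0, "onset"),
                      stim_dur = vapply(stim, `[[`, 0, "duration"),
                      stim_amp = vapply(stim, `[[`, 0, "amplitude"),
                      dt = config$dt, n_steps = n_steps,
                      sample_every = config$sample_every,
                      cg_tol = config$cg_tol, cg_maxit = config$cg_maxit,
                      reaction_on = reaction_on, check_extinction = TRUE,
                      ext_thresh = config$ext_threshold_mV,
                      ext_ms = config$ext_window_ms,
                      return_states = return_states)
  structure(list(movie = res$movie, times = res$times, dims = ops$dims,
                 dims_elem = ops$dims_elem, element_size = element_size,
                 duration_s = res$duration_s, termination = res$termination,
                 states = res$states, protocol = protocol, config = config,
                 geometry = if (inherits(geometry, "fs_slab_geometry"))
                   geometry else NULL),
            class = "fs_simulation_result")
}

#' @export
print.fs_simulation_result <- function(x, ...) {
  cat("<fs_simulation_result> ", paste(x$dims, collapse = " x "),
      " nodes, ", ncol(x$movie), " frames at ",
      x$config$output_rate_hz, " Hz\n",
      "  duration ", round(x$duration_s, 3), " s, termination: ",
      x$termination, "\n", sep = "")
  invisible(x)
}

#' Extract one sheet of the voltage movie
#'
#' @param result an `fs_simulation_result`.
#' @param sheet `"endo"` (node plane 1), `"epi"` (last node plane) or a
#'   node-plane index.
#' @return array `nx+1` x `ny+1` x frames.
#' @export
movie_sheet <- function(result, sheet = "endo") {
  dims <- result$dims
  k <- if (is.numeric(sheet)) as.integer(sheet)
       else switch(sheet, endo = 1L, epi = dims[3],
                   stop("unknown sheet '", sheet, "'"))
  n_plane <- dims[1] * dims[2]
  rows <- ((k - 1L) * n_plane + 1L):(k * n_plane)
  array(result$movie[rows, , drop = FALSE],
        dim = c(dims[1], dims[2], ncol(result$movie)))
}

#' Node mask from an element mask
#'
#' A node belongs to the mask when any of its adjacent elements does; used
#' to compare element-based geometry masks (patches) with node-based
#' simulation sheets.
#'
#' @param mask logical element matrix (`nx` x `ny`).
#' @return logical node matrix (`nx+1` x `ny+1`).
#' @export
element_mask_to_nodes <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  out <- matrix(FALSE, nx + 1, ny + 1)
  for (a in 0:1) for (b in 0:1) {
    out[(1:nx) + a, (1:ny) + b] <- out[(1:nx) + a, (1:ny) + b] | mask
  }
  out
}

#' Advance a tissue state by explicit reaction / implicit diffusion steps
#'
#' One (or a few) operator-split time steps from an explicit per-node state
#' matrix: forward-Euler reaction including stimulus and gap currents, then
#' the implicit conjugate-gradient diffusion sub-step.  Mainly useful for
#' inspecting the integrator; [run_simulation()] drives whole episodes.
#'
#' @param states 32 x n-nodes state matrix (e.g. the `states` field of a
#'   result run with `return_states = TRUE`).
#' @param geometry label array or `fs_slab_geometry` defining the mesh.
#' @param protocol an `fs_stim_protocol` (node-grid footprints).
#' @param config an `fs_solver_config`.
#' @param t0 simulation time of the first step (s), for stimulus windows.
#' @param n_steps number of `dt` steps to take.
#' @inheritParams run_simulation
#' @return the updated 32 x n-nodes state matrix.
#' @export
advance_time_step <- function(states, geometry, protocol,
                              config = solver_config(), t0 = 0, n_steps = 1,
                              params_myo = cell_params(numf = 3),
                              params_fib = cell_params(numf = 45),
                              sigma_mS_cm = c(MYO = 0.5, FIB_FL = 0.1,
                                              FIB_IL = 0),
                              element_size_mm = 0.4) {
  cfg <- config
  cfg$max_time <- n_steps * config$dt
  cfg$sample_every <- n_steps
  # shift stimulus windows so that "now" is t0
  prot <- protocol
  prot$stimuli <- lapply(prot$stimuli, function(s) {
    s$onset <- s$onset - t0
    s
  })
  r <- run_simulation(geometry, prot, cfg, params_myo = params_myo,
                      params_fib = params_fib, sigma_mS_cm = sigma_mS_cm,
                      element_size_mm = element_size_mm,
                      return_states = TRUE, init_states = states)
  r$states
}
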