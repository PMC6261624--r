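#' Electrode configuration
#'
#' Unipolar recording sites, bipolar pairs (6 mm interelectrode distance
#' under defaults), and the two pseudo-ECG sites 3 cm above the centers of
#' the endocardial and epicardial sheets.
#'
#' @param sites matrix (n x 3) of unipolar site positions in mm
#'   (slab coordinates; the tissue occupies `[0, L]` in x, y and z).
#' @param bipolar_pairs integer matrix (m x 2) of site-row indices.
#' @param ecg_sites 2 x 3 matrix: the endocardial-side and epicardial-side
#'   ECG electrode positions; `NULL` for none.
#' @param K dimensionless proportionality constant of the unipolar forward
#'   model.
#' @return list of class `fs_electrode_config`.
#' @export
electrode_config <- function(sites, bipolar_pairs = NULL, ecg_sites = NULL,
                             K = 1) {
  sites <- rbind(sites)
  stopifnot(ncol(sites) == 3)
  if (!is.null(bipolar_pairs)) {
    bipolar_pairs <- rbind(bipolar_pairs)
    stopifnot(ncol(bipolar_pairs) == 2,
              max(bipolar_pairs) <= nrow(sites))
  }
  structure(list(sites = sites, bipolar_pairs = bipolar_pairs,
                 ecg_sites = ecg_sites, K = K),
            class = "fs_electrode_config")
}

#' Default pseudo-ECG electrode positions for a mesh
#'
#' Two sites 3 cm outside the wall, above the centers of the endocardial
#' (z < 0 side) and epicardial sheets.
#' @param dims mesh dimensions.
#' @param element_size_mm element edge (mm).
#' @export
ecg_sites_default <- function(dims, element_size_mm = 0.4) {
  cx <- dims[1] * element_size_mm / 2
  cy <- dims[2] * element_size_mm / 2
  zt <- dims[3] * element_size_mm
  rbind(endo = c(cx, cy, -30), epi = c(cx, cy, zt + 30))
}

# Spatial gradient of one voltage frame by central differences; one-sided
# at mesh boundaries and across zero-conductivity elements so barriers do
# not produce spurious dipoles.
voltage_gradient <- function(frame, element_size_mm, sigma_zero = NULL) {
  dims <- dim(frame)
  h <- element_size_mm
  grad_axis <- function(axis) {
    n <- dims[axis]
    if (n == 1) return(array(0, dims))
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    idx_p <- pmin(seq_len(n) + 1L, n)
    sel <- function(i) switch(axis,
                              frame[i, , , drop = FALSE],
                              frame[, i, , drop = FALSE],
                              frame[, , i, drop = FALSE])
    up <- sel(idx_p); dn <- sel(idx_m)
    span <- array(rep((idx_p - idx_m) * h,
                      each = prod(dims[seq_len(axis - 1)])), dims)
    g <- (up - dn) / span
    if (!is.null(sigma_zero) && any(sigma_zero)) {
      zu <- sel(idx_p); zd <- sel(idx_m)
      zup <- switch(axis, sigma_zero[idx_p, , , drop = FALSE],
                    sigma_zero[, idx_p, , drop = FALSE],
                    sigma_zero[, , idx_p, drop = FALSE])
      zdn <- switch(axis, sigma_zero[idx_m, , , drop = FALSE],
                    sigma_zero[, idx_m, , drop = FALSE],
                    sigma_zero[, , idx_m, drop = FALSE])
      # one-sided where a neighbor is a barrier
      one_up <- zdn & !zup
      one_dn <- zup & !zdn
      g[one_up] <- ((zu - frame) / h)[one_up]
      g[one_dn] <- ((frame - zd) / h)[one_dn]
      g[zup & zdn] <- 0
      g[sigma_zero] <- 0
    }
    g
  }
  list(gx = grad_axis(1), gy = grad_axis(2), gz = grad_axis(3))
}

# Precompute per-site integration weights w = (r_site - r_el)/R^3 * dv.
site_weights <- function(site, dims, element_size_mm, min_R = NULL) {
  h <- element_size_mm
  if (is.null(min_R)) min_R <- h / 2
  cx <- (seq_len(dims[1]) - 0.5) * h
  cy <- (seq_len(dims[2]) - 0.5) * h
  cz <- (seq_len(dims[3]) - 0.5) * h
  dx <- array(site[1] - cx, dims)
  dy <- array(rep(site[2] - cy, each = dims[1]), dims)
  dz <- array(rep(site[3] - cz, each = dims[1] * dims[2]), dims)
  R <- sqrt(dx^2 + dy^2 + dz^2)
  close_by <- R < min_R
  if (any(close_by)) {
    warning(sum(close_by), " element(s) within ", min_R,
            " mm of the recording site excluded from the Eq-6 sum",
            call. = FALSE)
  }
  R3 <- R^3
  dv <- h^3
  w <- list(x = dx / R3 * dv, y = dy / R3 * dv, z = dz / R3 * dv)
  for (nm in names(w)) w[[nm]][close_by] <- 0
  w
}

#' Unipolar electrogram of one voltage frame
#'
#' Discrete evaluation of the unbounded-volume-conductor integral
#' `Phi_e(r) = -K sum grad(Vmyo) . grad(1/R) dv` over the tissue elements,
#' with the transmembrane gradient estimated by central differences
#' (one-sided at boundaries and across zero-conductivity barriers).
#'
#' @param frame voltage array `nx` x `ny` x `nz` (mV).
#' @param site numeric length-3 recording position (mm).
#' @param element_size_mm element edge (mm).
#' @param K proportionality constant.
#' @param sigma_zero optional logical array of zero-conductivity elements.
#' @return scalar potential (arbitrary units proportional to mV.mm).
#' @export
compute_unipolar <- function(frame, site, element_size_mm = 0.4, K = 1,
                             sigma_zero = NULL) {
  g <- voltage_gradient(frame, element_size_mm, sigma_zero)
  w <- site_weights(site, dim(frame), element_size_mm)
  -K * sum(g$gx * w$x + g$gy * w$y + g$gz * w$z)
}

#' Bipolar electrogram from two unipolar signals
#'
#' @param unipolar_a,unipolar_b equal-length numeric signals.
#' @return their per-sample difference `a - b`.
#' @export
compute_bipolar <- function(unipolar_a, unipolar_b) {
  if (length(unipolar_a) != length(unipolar_b)) {
    stop("unipolar signals differ in length", call. = FALSE)
  }
  unipolar_a - unipolar_b
}

#' Unipolar electrogram time series at multiple sites
#'
#' @param result an `fs_simulation_result`.
#' @param config an `fs_electrode_config`.
#' @return matrix frames x sites of unipolar potentials at 1 kHz.
#' @export
electrogram_signals <- function(result, config) {
  dims <- result$dims
  h <- result$element_size
  sigma_zero <- NULL
  if (!is.null(result$geometry)) {
    lab <- result$geometry$labels
    if (!identical(dim(lab), as.integer(dims))) {
      lab <- node_labels(lab)  # movie lives on the node grid
    }
    sigma_zero <- array(lab == TISSUE_FIB_IL, dim = dims)
  }
  ws <- lapply(seq_len(nrow(config$sites)), function(i) {
    site_weights(config$sites[i, ], dims, h)
  })
  nT <- ncol(result$movie)
  out <- matrix(0, nT, nrow(config$sites))
  for (t in seq_len(nT)) {
    fr <- array(result$movie[, t], dim = dims)
    g <- voltage_gradient(fr, h, sigma_zero)
    for (i in seq_along(ws)) {
      w <- ws[[i]]
      out[t, i] <- -config$K *
        sum(g$gx * w$x + g$gy * w$y + g$gz * w$z)
    }
  }
  colnames(out) <- rownames(config$sites)
  out
}

#' Pseudo-ECG of a simulation
#'
#' Difference of the two far-field unipolar electrograms recorded 3 cm
#' outside the endocardial and epicardial sheet centers.
#'
#' @param result an `fs_simulation_result`.
#' @param config electrode configuration; its `ecg_sites` (or the default
#'   positions) are used.
#' @return numeric signal at 1 kHz (endocardial minus epicardial side).
#' @export
compute_pseudo_ecg <- function(result, config = NULL) {
  sites <- if (!is.null(config) && !is.null(config$ecg_sites)) {
    config$ecg_sites
  } else {
    ecg_sites_default(result$dims, result$element_size)
  }
  K <- if (!is.null(config)) config$K else 1
  sig <- electrogram_signals(result, electrode_config(sites, K = K))
  sig[, 1] - sig[, 2]
}

#' Power spectra and spectral maxima of recorded signals
#'
#' Periodogram of each (mean-removed) signal; normalized so the summed
#' spectrum equals the signal variance (Parseval).  Returns per signal the
#' spectrum, its maximum and the frequency of the maximum.
#'
#' @param signals numeric vector or matrix (time x sites), sampled at `fs`.
#' @param fs sampling rate (Hz), 1 kHz default.
#' @return list of class `fs_power_spectrum`: `freq`, `power` (freq x
#'   sites), `max_power`, `max_freq` (NA for all-zero signals).
#' @export
power_spectrum_map <- function(signals, fs = 1000) {
  signals <- cbind(signals)
  n <- nrow(signals)
  if (n < fs) stop("need at least 1 s of signal", call. = FALSE)
  x <- sweep(signals, 2, colMeans(signals))
  P <- abs(stats::mvfft(x))^2 / n^2
  nf <- floor(n / 2)
  freq <- (seq_len(nf)) * fs / n
  # fold negative frequencies so total power is preserved
  Pf <- P[2:(nf + 1), , drop = FALSE]
  if (n %% 2 == 0) {
    Pf[-nf, ] <- Pf[-nf, , drop = FALSE] + P[n:(nf + 2), , drop = FALSE]
  } else {
    Pf <- Pf + P[n:(nf + 2), , drop = FALSE]
  }
  max_i <- apply(Pf, 2, which.max)
  max_p <- Pf[cbind(max_i, seq_len(ncol(Pf)))]
  max_f <- freq[max_i]
  max_f[max_p == 0] <- NA_real_
  list(freq = freq, power = Pf, max_power = max_p, max_freq = max_f)
}
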