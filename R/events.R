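#' Newly activated connected components per frame
#'
#' An element "activates" when its voltage crosses the activation threshold
#' upward between consecutive frames.  Newly activated elements of one
#' frame are grouped by in-plane 8-connectivity; each component records the
#' previous-frame active components it touches (its parents).  Breakthrough
#' candidates are components without parents.
#'
#' @param sheet voltage array `nx` x `ny` x frames.
#' @param threshold_mV activation threshold (upward crossing), -40 mV
#'   default.
#' @return list of per-frame lists of components; each component is a list
#'   with `frame`, `elements` (flat in-plane indices), `n_parents`.
#' @export
detect_activation_components <- function(sheet, threshold_mV = -40) {
  dims <- dim(sheet)
  nx <- dims[1]; ny <- dims[2]; nT <- dims[3]
  act <- sheet >= threshold_mV
  out <- vector("list", nT)
  out[[1]] <- list()
  prev_active <- matrix(FALSE, nx, ny)
  for (t in 2:nT) {
    newly <- act[, , t] & !act[, , t - 1]
    comps <- list()
    if (any(newly)) {
      lab <- label_patches(newly)
      # previous-frame active region dilated by one element (8-neighborhood)
      prev <- act[, , t - 1]
      prev_dil <- dilate8(prev)
      for (id in seq_len(max(lab))) {
        el <- which(lab == id)
        comps[[id]] <- list(frame = t, elements = el,
                            n_parents = as.integer(any(prev_dil[el])))
      }
    }
    out[[t]] <- comps
  }
  out
}

dilate8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  out <- mask
  sh <- function(di, dj) {
    m <- matrix(FALSE, nx, ny)
    si <- max(1, 1 + di):min(nx, nx + di)
    sj <- max(1, 1 + dj):min(ny, ny + dj)
    m[si, sj] <- mask[si - di, sj - dj]
    m
  }
  for (di in -1:1) for (dj in -1:1) {
    if (di || dj) out <- out | sh(di, dj)
  }
  out
}

#' Detect breakthrough events on a surface sheet
#'
#' A breakthrough is a wavefront appearing on the endocardial or epicardial
#' sheet with no parent wave in that sheet, over the in-plane projection of
#' a myocardial patch of the isolation layers (the only transmural routes).
#' It is veritable if its descendants grow to at least `extent_min`
#' elements or merge with another wave before dying out; otherwise it is
#' recorded as annihilated.
#'
#' @param sheet voltage array of the monitored surface sheet.
#' @param geometry the `fs_slab_geometry` (for myocardial patch
#'   projections); `NULL` accepts any parentless component (testing).
#' @param which_sheet `"endo"` or `"epi"` (selects the adjacent isolation
#'   layer).
#' @param threshold_mV activation threshold.
#' @param extent_min element count a breakthrough wave must reach to be
#'   veritable (about 4 mm^2 at 0.4 mm pitch).
#' @param follow_ms frames over which descendants are followed.
#' @return data.frame with one row per candidate: `onset_frame`, `x`, `y`
#'   (mm, onset centroid), `seed_patch`, `veritable`, `extent`,
#'   `survival_ms`.
#' @export
detect_breakthroughs <- function(sheet, geometry = NULL,
                                 which_sheet = c("endo", "epi"),
                                 threshold_mV = -40, extent_min = 25,
                                 follow_ms = 50) {
  which_sheet <- match.arg(which_sheet)
  dims <- dim(sheet)
  nx <- dims[1]; ny <- dims[2]; nT <- dims[3]
  h <- if (!is.null(geometry)) geometry$stack$element_size else 0.4
  patch_lab <- NULL
  if (!is.null(geometry)) {
    iso <- slice_index(geometry$stack,
                       if (which_sheet == "endo") "ISO_UPPER" else "ISO_LOWER")
    myo_mask <- geometry$labels[, , iso] == TISSUE_MYO
    patch_lab <- label_patches(myo_mask)
    if (all(dim(sheet)[1:2] == dim(myo_mask) + 1L)) {
      # node-grid sheet: a node carries the patch id of any adjacent element
      pl <- matrix(0L, nx, ny)
      for (a in 0:1) for (b in 0:1) {
        sub <- pl[(1:nrow(myo_mask)) + a, (1:ncol(myo_mask)) + b]
        pl[(1:nrow(myo_mask)) + a, (1:ncol(myo_mask)) + b] <-
          pmax(sub, patch_lab)
      }
      patch_lab <- pl
    }
  }
  comps <- detect_activation_components(sheet, threshold_mV)
  act <- sheet >= threshold_mV
  res <- list()
  for (t in seq_along(comps)) {
    for (cp in comps[[t]]) {
      if (cp$n_parents > 0) next
      seed <- NA_integer_
      if (!is.null(patch_lab)) {
        over <- patch_lab[cp$elements]
        over <- over[over > 0]
        if (!length(over)) next  # not a transmural penetration
        seed <- as.integer(names(sort(table(over), decreasing = TRUE))[1])
      }
      # follow the wave grown from this component
      wave <- matrix(FALSE, nx, ny)
      wave[cp$elements] <- TRUE
      extent <- sum(wave)
      merged <- FALSE
      survival <- 0L
      for (tf in (t + 1):min(t + follow_ms, nT)) {
        if (tf > nT) break
        grown <- dilate8(wave) & act[, , tf]
        # merge: the grown wave touches activity not its own
        other <- act[, , tf] & !dilate8(wave)
        touch <- dilate8(grown) & other
        if (any(touch)) merged <- TRUE
        if (!any(grown)) break
        wave <- grown
        extent <- max(extent, sum(wave))
        survival <- survival + 1L
        if (merged || extent >= extent_min) break
      }
      ctr <- arrayInd(cp$elements, c(nx, ny))
      res[[length(res) + 1]] <- data.frame(
        onset_frame = t,
        x = mean((ctr[, 1] - 0.5) * h), y = mean((ctr[, 2] - 0.5) * h),
        seed_patch = seed,
        veritable = merged || extent >= extent_min,
        extent = extent, survival_ms = survival)
    }
  }
  if (!length(res)) {
    return(data.frame(onset_frame = integer(0), x = numeric(0),
                      y = numeric(0), seed_patch = integer(0),
                      veritable = logical(0), extent = integer(0),
                      survival_ms = integer(0)))
  }
  do.call(rbind, res)
}

#' Per-element breakthrough count map
#'
#' @param events data.frame from [detect_breakthroughs()].
#' @param dims in-plane dimensions `c(nx, ny)`.
#' @param element_size_mm element edge (mm).
#' @param window_s optional `c(t0, t1)` onset-time window in seconds
#'   (frames are 1 ms).
#' @param veritable_only count only veritable breakthroughs.
#' @return integer `nx` x `ny` count matrix.
#' @export
breakthrough_location_map <- function(events, dims, element_size_mm = 0.4,
                                      window_s = NULL, veritable_only = TRUE) {
  m <- matrix(0L, dims[1], dims[2])
  if (!nrow(events)) return(m)
  keep <- rep(TRUE, nrow(events))
  if (veritable_only) keep <- keep & events$veritable
  if (!is.null(window_s)) {
    t_s <- events$onset_frame / 1000
    keep <- keep & t_s >= window_s[1] & t_s <= window_s[2]
  }
  ev <- events[keep, , drop = FALSE]
  for (r in seq_len(nrow(ev))) {
    i <- pmin(pmax(round(ev$x[r] / element_size_mm + 0.5), 1), dims[1])
    j <- pmin(pmax(round(ev$y[r] / element_size_mm + 0.5), 1), dims[2])
    m[i, j] <- m[i, j] + 1L
  }
  m
}

#' Detect intramural re-entry
#'
#' Two-stage detection of an activation loop inside the connection wall.
#' Stage 1 screens for isolation-layer myocardial patches that seed at
#' least `min_cycles` successive breakthroughs at a fixed location with
#' period dispersion below `period_tol`; a re-entry needs such periodic
#' anchors on both surfaces.  Stage 2 confirms a transmural circuit: for
#' each cycle, the activation-time-ordered path of connection-wall elements
#' linking the endocardial and epicardial anchor patches must re-activate
#' as a closed 26-connected loop with the anchor period.
#'
#' @param result an `fs_simulation_result` carrying its geometry.
#' @param breakthrough_args passed to [detect_breakthroughs()].
#' @param min_cycles minimal repeats to call periodicity (3).
#' @param period_tol relative period dispersion tolerance (0.1).
#' @param threshold_mV activation threshold used for circuit tracing.
#' @return data.frame with one row per re-entry: `endo_patch`, `epi_patch`,
#'   `period_ms`, `n_cycles`, `first_frame`, `last_frame`,
#'   `circuit_confirmed`.
#' @export
detect_intramural_reentry <- function(result, breakthrough_args = list(),
                                      min_cycles = 3, period_tol = 0.1,
                                      threshold_mV = -40) {
  geometry <- result$geometry
  if (is.null(geometry)) stop("result carries no geometry", call. = FALSE)
  anchors <- list()
  for (sheet_name in c("endo", "epi")) {
    sh <- movie_sheet(result, sheet_name)
    ev <- do.call(detect_breakthroughs,
                  c(list(sh, geometry, sheet_name), breakthrough_args))
    ev <- ev[ev$veritable, , drop = FALSE]
    if (!nrow(ev)) next
    for (pid in unique(ev$seed_patch)) {
      on <- sort(ev$onset_frame[ev$seed_patch == pid])
      if (length(on) < min_cycles) next
      gaps <- diff(on)
      if (!length(gaps)) next
      if (stats::sd(gaps) / mean(gaps) < period_tol ||
          (length(gaps) == 1)) {
        anchors[[length(anchors) + 1]] <- list(
          sheet = sheet_name, patch = pid, period = mean(gaps),
          first = on[1], last = on[length(on)], n = length(on))
      }
    }
  }
  endo_a <- Filter(function(a) a$sheet == "endo", anchors)
  epi_a <- Filter(function(a) a$sheet == "epi", anchors)
  res <- list()
  for (ea in endo_a) {
    for (pa in epi_a) {
      if (abs(ea$period - pa$period) / mean(c(ea$period, pa$period)) >
          period_tol) next
      confirmed <- confirm_transmural_circuit(result, ea, pa, threshold_mV)
      res[[length(res) + 1]] <- data.frame(
        endo_patch = ea$patch, epi_patch = pa$patch,
        period_ms = mean(c(ea$period, pa$period)),
        n_cycles = min(ea$n, pa$n),
        first_frame = min(ea$first, pa$first),
        last_frame = max(ea$last, pa$last),
        circuit_confirmed = confirmed)
    }
  }
  if (!length(res)) {
    return(data.frame(endo_patch = integer(0), epi_patch = integer(0),
                      period_ms = numeric(0), n_cycles = integer(0),
                      first_frame = integer(0), last_frame = integer(0),
                      circuit_confirmed = logical(0)))
  }
  do.call(rbind, res)
}

# Stage 2: within one anchor period, connection-wall activity must form a
# 26-connected component that touches both anchor patches' projections in
# the wall, in at least min_cycles consecutive cycles.
confirm_transmural_circuit <- function(result, endo_anchor, epi_anchor,
                                       threshold_mV) {
  geometry <- result$geometry
  dims <- result$dims
  stack <- geometry$stack
  node_grid <- dims[3] == nrow(stack$slices) + 1L
  wall <- 2:(dims[3] - 1)  # interior planes (exclude the two surfaces)
  iso_up <- slice_index(stack, "ISO_UPPER")
  iso_lo <- slice_index(stack, "ISO_LOWER")
  lab_up <- label_patches(geometry$labels[, , iso_up] == TISSUE_MYO)
  lab_lo <- label_patches(geometry$labels[, , iso_lo] == TISSUE_MYO)
  up_mask <- lab_up == endo_anchor$patch
  lo_mask <- lab_lo == epi_anchor$patch
  if (node_grid) {
    up_mask <- element_mask_to_nodes(up_mask)
    lo_mask <- element_mask_to_nodes(lo_mask)
    up_planes <- c(iso_up, iso_up + 1L)       # node planes bounding the slice
    lo_planes <- c(iso_lo, iso_lo + 1L)
  } else {
    up_planes <- iso_up
    lo_planes <- iso_lo
  }
  up_idx <- match(intersect(up_planes, wall), wall)
  lo_idx <- match(intersect(lo_planes, wall), wall)
  period <- round(mean(c(endo_anchor$period, epi_anchor$period)))
  t0 <- min(endo_anchor$first, epi_anchor$first)
  nT <- ncol(result$movie)
  n_ok <- 0
  cycles <- 0
  t <- t0
  while (t + period - 1 <= nT && cycles < 4) {
    frames <- t:(t + period - 1)
    vol <- array(result$movie[, frames], dim = c(dims, length(frames)))
    # activated anywhere in the cycle, wall planes only
    act3 <- apply(vol[, , wall, , drop = FALSE] >= threshold_mV, 1:3, any)
    comp <- connected3d(act3)
    ok <- FALSE
    if (max(comp) > 0) {
      for (id in seq_len(max(comp))) {
        cmask <- comp == id
        touches_up <- any(cmask[, , up_idx, drop = FALSE] &
                            as.vector(up_mask))
        touches_lo <- any(cmask[, , lo_idx, drop = FALSE] &
                            as.vector(lo_mask))
        if (touches_up && touches_lo) { ok <- TRUE; break }
      }
    }
    if (ok) n_ok <- n_ok + 1
    cycles <- cycles + 1
    t <- t + period
  }
  cycles > 0 && n_ok == cycles
}

# 26-connected components of a 3D logical array (iterative flood fill).
connected3d <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nlab <- 0L
  nxy <- dims[1] * dims[2]
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- ((cur - 1L) %/% nxy) + 1L
      rem <- (cur - 1L) %% nxy
      j <- (rem %/% dims[1]) + 1L
      i <- (rem %% dims[1]) + 1L
      ni <- i + offs[, 1]; nj <- j + offs[, 2]; nk <- k + offs[, 3]
      keep <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
              nk >= 1 & nk <= dims[3]
      nb <- (nk[keep] - 1L) * nxy + (nj[keep] - 1L) * dims[1] + ni[keep]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nlab
        queue <- c(queue, nb)
      }
    }
  }
  lab
}
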