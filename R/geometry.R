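# Intramural fibrosis windows (IFD %, lo-hi) controlled by the fibrotic blob
# count per thick fibrotic layer, for each simulation group.
IFD_WINDOWS <- list(
  STOCHASTIC = data.frame(
    n_fib = c(26, 30, 34, 38, 42, 46, 50),
    lo = c(21.5, 24.5, 28.0, 31.0, 34.4, 37.8, 40.7),
    hi = c(22.5, 25.5, 29.0, 32.0, 35.4, 38.8, 41.7)),
  INTERRELATED = data.frame(
    n_fib = c(26, 30, 34, 38, 42, 46, 50, 55),
    lo = c(22.0, 25.0, 28.0, 32.0, 35.0, 37.5, 40.5, 44.5),
    hi = c(24.0, 27.0, 30.0, 34.0, 37.0, 39.5, 42.5, 46.5)),
  FIBROSIS_CONTROLLED = data.frame(
    n_fib = c(30, 38, 42, 46, 55),
    lo = c(25.5, 32.5, 35.5, 38.0, 44.5),
    hi = c(26.5, 33.5, 36.5, 39.0, 45.5)),
  DISSOCIATION_CONTROLLED = data.frame(
    n_fib = c(30, 34, 38, 44, 50),
    lo = c(24.5, 28.5, 32.5, 37.0, 41.5),
    hi = c(25.5, 29.5, 33.5, 38.0, 42.5))
)

# The 13 (n_myo, n_fib) pairs of an interrelated series.
INTERRELATED_PAIRS <- data.frame(
  n_myo = 5:17,
  n_fib = c(55, 46, 50, 42, 46, 38, 42, 34, 38, 30, 34, 26, 30))

# Per-group (n_myo, n_fib) pairs for the controlled groups (12 replicates each).
FIBROSIS_CONTROLLED_PAIRS <- data.frame(
  n_myo = c(5, 7, 9, 11, 13), n_fib = c(55, 38, 42, 46, 30))
DISSOCIATION_CONTROLLED_PAIRS <- data.frame(
  n_myo = c(7, 9, 10, 11, 13), n_fib = c(50, 34, 38, 44, 30))

#' IFD acceptance window for a group and fibrotic blob count
#'
#' Returns the controlled intramural-fibrosis-degree window (percent) for
#' the given fibrotic blob count per thick fibrotic layer.  Counts between
#' tabulated rows (possible in the stochastic group, whose counts range over
#' 26-50) are linearly interpolated between neighboring rows.
#'
#' @param group_kind one of `"STOCHASTIC"`, `"INTERRELATED"`,
#'   `"FIBROSIS_CONTROLLED"`, `"DISSOCIATION_CONTROLLED"`.
#' @param n_fib fibrotic blob count per thick fibrotic layer.
#' @return numeric length-2 `c(lo, hi)` in percent.
#' @export
ifd_window <- function(group_kind, n_fib) {
  tab <- IFD_WINDOWS[[match.arg(group_kind, names(IFD_WINDOWS))]]
  if (n_fib < min(tab$n_fib) || n_fib > max(tab$n_fib)) {
    stop("fibrotic blob count ", n_fib, " outside the tabulated range [",
         min(tab$n_fib), ", ", max(tab$n_fib), "]", call. = FALSE)
  }
  c(lo = stats::approx(tab$n_fib, tab$lo, xout = n_fib)$y,
    hi = stats::approx(tab$n_fib, tab$hi, xout = n_fib)$y)
}

#' Simulation-group configuration
#'
#' Describes how geometries of one of the four study groups are drawn:
#' blob counts per layer, the controlled IFD window, and (for the
#' dissociation-degree-controlled group) the shared myocardial layout.
#'
#' @param group_kind group name; see [ifd_window()].
#' @param n_myo myocardial blob count per isolation layer.  For the
#'   stochastic group `NULL` means "draw uniformly from 5-19 per geometry".
#' @param n_fib fibrotic blob count per thick fibrotic layer (26-50 for the
#'   stochastic group).
#' @param stack an `fs_layer_stack`; defaults to the 40 x 40 x 3.6 mm slab.
#' @param myo_radius,fib_radius blob radii in mm.
#' @param balance balance parameters, see [balance_params()].
#' @param max_geometries rejection-sampling budget against the IFD window.
#' @param ifd_window explicit `c(lo, hi)` acceptance window in percent;
#'   `NULL` looks up the controlled window for `n_fib`.  Desk-scale
#'   footprints, whose coverage fractions differ from the 40 mm slab,
#'   should pass an explicit window (or `c(0, 100)`).
#' @param fixed_myo_blobs optional list of two blob data.frames (upper and
#'   lower isolation layers) shared by all replicates of a
#'   dissociation-degree-controlled group.
#' @return an object of class `fs_group_config`.
#' @export
group_config <- function(group_kind = c("STOCHASTIC", "INTERRELATED",
                                        "FIBROSIS_CONTROLLED",
                                        "DISSOCIATION_CONTROLLED"),
                         n_myo = NULL, n_fib = 26,
                         stack = build_layer_stack(),
                         myo_radius = 2.5, fib_radius = 2.6,
                         balance = balance_params(stack),
                         max_geometries = 500L,
                         fixed_myo_blobs = NULL, ifd_window = NULL) {
  group_kind <- match.arg(group_kind)
  if (is.null(n_myo) && group_kind != "STOCHASTIC") {
    stop("n_myo must be given for non-stochastic groups", call. = FALSE)
  }
  window <- if (is.null(ifd_window)) {
    fibroslab::ifd_window(group_kind, n_fib)
  } else {
    stopifnot(length(ifd_window) == 2, ifd_window[1] <= ifd_window[2])
    ifd_window
  }
  structure(list(group_kind = group_kind, n_myo = n_myo, n_fib = n_fib,
                 stack = stack, myo_radius = myo_radius,
                 fib_radius = fib_radius, balance = balance,
                 ifd_window = window,
                 max_geometries = as.integer(max_geometries),
                 fixed_myo_blobs = fixed_myo_blobs),
            class = "fs_group_config")
}

#' @export
print.fs_group_config <- function(x, ...) {
  cat("<fs_group_config> ", x$group_kind,
      ": n_myo = ", if (is.null(x$n_myo)) "5-19 (drawn)" else x$n_myo,
      ", n_fib = ", x$n_fib,
      ", IFD window [", x$ifd_window[1], ", ", x$ifd_window[2], "] %\n",
      sep = "")
  invisible(x)
}

# Assemble the per-element label array from per-layer in-plane masks.
assemble_labels <- function(stack, iso_upper_myo, iso_lower_myo,
                            thick_upper_fib, thick_lower_fib) {
  nz <- nrow(stack$slices)
  labels <- array(TISSUE_MYO, dim = c(stack$nx, stack$ny, nz))
  thin <- derive_thin_fibrotic_mask(thick_upper_fib, thick_lower_fib)
  for (s in seq_len(nz)) {
    kind <- stack$slices$kind[s]
    if (kind == "ISOLATION") {
      myo <- if (s == slice_index(stack, "ISO_UPPER")) iso_upper_myo else iso_lower_myo
      labels[, , s][!myo] <- TISSUE_FIB_IL
    } else if (kind == "THICK_FIBROTIC") {
      fib <- if (s %in% slice_index(stack, "THICK_UPPER")) thick_upper_fib else thick_lower_fib
      labels[, , s][fib] <- TISSUE_FIB_FL
    } else if (kind == "THIN_FIBROTIC") {
      labels[, , s][thin] <- TISSUE_FIB_FL
    }
  }
  labels
}

#' Intramural fibrosis degree (percent)
#'
#' The percentage of elements in the fibrotic layers (both thick fibrotic
#' layers and the thin fibrotic layer) that are fibrotic tissue.
#'
#' @param geometry an `fs_slab_geometry`.
#' @return percentage in `[0, 100]`.
#' @export
compute_ifd <- function(geometry) {
  sl <- slice_index(geometry$stack, "FIBROTIC_ALL")
  sub <- geometry$labels[, , sl, drop = FALSE]
  100 * sum(sub == TISSUE_FIB_FL) / length(sub)
}

#' Endo-epicardial dissociation degree (percent)
#'
#' The percentage of elements in the two isolation layers that are fibrotic
#' tissue (the complement of the transmural conduction routes).
#'
#' @param geometry an `fs_slab_geometry`.
#' @return percentage in `[0, 100]`.
#' @export
compute_edd <- function(geometry) {
  sl <- slice_index(geometry$stack, "ISO_ALL")
  sub <- geometry$labels[, , sl, drop = FALSE]
  100 * sum(sub == TISSUE_FIB_IL) / length(sub)
}

# Build one geometry realization from explicit blob sets (no IFD rejection).
build_geometry_from_blobs <- function(stack, myo_upper, myo_lower,
                                      fib_upper, fib_lower, seed = NA) {
  iso_up <- rasterize_blobs(myo_upper, stack)
  iso_lo <- rasterize_blobs(myo_lower, stack)
  f_up <- rasterize_blobs(fib_upper, stack)
  f_lo <- rasterize_blobs(fib_lower, stack)
  geom <- structure(
    list(stack = stack,
         labels = assemble_labels(stack, iso_up, iso_lo, f_up, f_lo),
         blobs = list(myo_upper = myo_upper, myo_lower = myo_lower,
                      fib_upper = fib_upper, fib_lower = fib_lower),
         seed = seed),
    class = "fs_slab_geometry")
  geom$ifd <- compute_ifd(geom)
  geom$edd <- compute_edd(geom)
  geom
}

#' Generate one accepted slab geometry for a simulation group
#'
#' Composes blob sampling, rasterization, the projection constraint
#' (fibrotic patches may not obstruct myocardial patches of the adjacent
#' isolation layer), and the thin-layer derivation, then rejects whole
#' geometries until the realized IFD falls inside the group's controlled
#' window for the configured fibrotic blob count.  EDD is recorded but
#' never targeted.
#'
#' @param config an `fs_group_config`.
#' @param seed integer RNG seed; the result is a pure function of
#'   `(config, seed)`.
#' @return an object of class `fs_slab_geometry` with fields `stack`,
#'   `labels` (nx x ny x 9 integer array of tissue classes), `blobs`,
#'   `ifd`, `edd`, `seed`, `n_myo`, `n_fib`, `group_kind`, `attempts`.
#' @export
generate_geometry <- function(config, seed) {
  stopifnot(inherits(config, "fs_group_config"))
  set.seed(seed)
  stack <- config$stack
  window <- config$ifd_window
  realized <- numeric(0)
  for (attempt in seq_len(config$max_geometries)) {
    n_myo <- if (is.null(config$n_myo)) sample(5:19, 1) else config$n_myo
    if (!is.null(config$fixed_myo_blobs)) {
      myo_up <- config$fixed_myo_blobs[[1]]
      myo_lo <- config$fixed_myo_blobs[[2]]
      n_myo <- nrow(myo_up)
    } else {
      myo_up <- sample_blob_set(stack, n_myo, config$myo_radius, "MYOCARDIAL",
                                slice_index(stack, "ISO_UPPER"), config$balance)
      myo_lo <- sample_blob_set(stack, n_myo, config$myo_radius, "MYOCARDIAL",
                                slice_index(stack, "ISO_LOWER"), config$balance)
    }
    iso_up <- rasterize_blobs(myo_up, stack)
    iso_lo <- rasterize_blobs(myo_lo, stack)
    fib_up <- sample_blob_set(stack, config$n_fib, config$fib_radius,
                              "FIBROTIC", slice_index(stack, "THICK_UPPER")[1],
                              config$balance)
    fib_lo <- sample_blob_set(stack, config$n_fib, config$fib_radius,
                              "FIBROTIC", slice_index(stack, "THICK_LOWER")[1],
                              config$balance)
    fib_up <- enforce_projection_constraint(fib_up, iso_up, stack)
    fib_lo <- enforce_projection_constraint(fib_lo, iso_lo, stack)
    geom <- build_geometry_from_blobs(stack, myo_up, myo_lo, fib_up, fib_lo,
                                      seed = seed)
    if (geom$ifd >= window[1] && geom$ifd <= window[2]) {
      geom$group_kind <- config$group_kind
      geom$n_myo <- n_myo
      geom$n_fib <- config$n_fib
      geom$attempts <- attempt
      return(geom)
    }
    realized <- c(realized, geom$ifd)
  }
  stop("no geometry with IFD in [", window[1], ", ", window[2], "] % after ",
       config$max_geometries, " attempts; realized IFD spanned [",
       round(min(realized), 2), ", ", round(max(realized), 2),
       "] % (median ", round(stats::median(realized), 2), " %)",
       call. = FALSE)
}

#' @export
print.fs_slab_geometry <- function(x, ...) {
  cat("<fs_slab_geometry> ", x$stack$nx, " x ", x$stack$ny, " x ",
      nrow(x$stack$slices), " elements",
      if (!is.null(x$group_kind)) paste0(" (", x$group_kind, ")"), "\n",
      "  IFD = ", round(x$ifd, 2), " %, EDD = ", round(x$edd, 2), " %",
      if (!is.null(x$n_myo)) paste0(", n_myo = ", x$n_myo,
                                    ", n_fib = ", x$n_fib), "\n", sep = "")
  invisible(x)
}

#' Generate the replicate set of a controlled group
#'
#' Fibrosis-degree-controlled replicates redraw both blob families each
#' time; dissociation-degree-controlled replicates share one fixed
#' myocardial blob layout (drawn once from the first seed) and redraw only
#' the fibrotic blobs.
#'
#' @param group_kind `"FIBROSIS_CONTROLLED"` or `"DISSOCIATION_CONTROLLED"`.
#' @param n_myo,n_fib the group's blob counts (one of the printed pairs).
#' @param n_replicates number of replicates (12 in the study design).
#' @param seed base seed; replicate i uses `seed + i - 1`.
#' @param ... passed to [group_config()].
#' @return list of `fs_slab_geometry`.
#' @export
generate_controlled_replicates <- function(group_kind, n_myo, n_fib,
                                           n_replicates = 12L, seed = 1L, ...) {
  group_kind <- match.arg(group_kind,
                          c("FIBROSIS_CONTROLLED", "DISSOCIATION_CONTROLLED"))
  cfg <- group_config(group_kind, n_myo = n_myo, n_fib = n_fib, ...)
  fixed <- NULL
  if (group_kind == "DISSOCIATION_CONTROLLED") {
    set.seed(seed)
    stack <- cfg$stack
    fixed <- list(
      sample_blob_set(stack, n_myo, cfg$myo_radius, "MYOCARDIAL",
                      slice_index(stack, "ISO_UPPER"), cfg$balance),
      sample_blob_set(stack, n_myo, cfg$myo_radius, "MYOCARDIAL",
                      slice_index(stack, "ISO_LOWER"), cfg$balance))
    cfg$fixed_myo_blobs <- fixed
  }
  lapply(seq_len(n_replicates), function(i) {
    generate_geometry(cfg, seed = seed + i - 1L)
  })
}
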