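# Draw a single uniform blob position honoring the edge margin.
sample_blob_position <- function(stack, radius) {
  Lx <- stack$nx * stack$element_size
  Ly <- stack$ny * stack$element_size
  m <- radius / 2
  c(runif(1, m, Lx - m), runif(1, m, Ly - m))
}

add_blobs <- function(blobs, stack, k, radius, kind, host_layer) {
  for (i in seq_len(k)) {
    p <- sample_blob_position(stack, radius)
    blobs <- rbind(blobs, data.frame(x = p[1], y = p[2], radius = radius,
                                     kind = kind, host_layer = host_layer,
                                     stringsAsFactors = FALSE))
  }
  blobs
}

#' Derive an interrelated geometry series by incremental blob editing
#'
#' Starting from a base geometry (the first printed parameter pair), each
#' subsequent member is produced from its predecessor by adding new
#' myocardial blobs and adding or removing fibrotic blobs so that the
#' per-layer counts match the next printed pair.  Removal always takes the
#' highest-indexed blobs, so the lowest-indexed blobs form a common core
#' shared by every member of the series.  After each edit the projection
#' constraint is re-enforced (only offending fibrotic blobs move) and the
#' member is locally resampled -- edited blobs first, non-core blobs as a
#' fallback -- until its IFD lies in the interrelated-group window for its
#' fibrotic blob count.
#'
#' @param base_geometry an accepted `fs_slab_geometry` whose blob counts
#'   match the first row of `param_pairs`.
#' @param param_pairs data.frame with columns `n_myo`, `n_fib`; defaults to
#'   the 13 printed pairs (5,55) ... (17,30).
#' @param seed RNG seed for the edits.
#' @param max_retries local-resampling budget per member.
#' @return list of `fs_slab_geometry`, one per pair (the first is the base).
#' @export
derive_interrelated_series <- function(base_geometry,
                                       param_pairs = INTERRELATED_PAIRS,
                                       seed = 1L, max_retries = 200L) {
  stopifnot(inherits(base_geometry, "fs_slab_geometry"))
  stack <- base_geometry$stack
  if (nrow(base_geometry$blobs$myo_upper) != param_pairs$n_myo[1] ||
      nrow(base_geometry$blobs$fib_upper) != param_pairs$n_fib[1]) {
    stop("base geometry blob counts do not match the first parameter pair",
         call. = FALSE)
  }
  set.seed(seed)
  core_fib <- min(param_pairs$n_fib)  # never-removed common core size
  series <- vector("list", nrow(param_pairs))
  base_geometry$group_kind <- "INTERRELATED"
  base_geometry$n_myo <- param_pairs$n_myo[1]
  base_geometry$n_fib <- param_pairs$n_fib[1]
  series[[1]] <- base_geometry
  cur <- base_geometry$blobs
  for (p in 2:nrow(param_pairs)) {
    d_myo <- param_pairs$n_myo[p] - param_pairs$n_myo[p - 1]
    d_fib <- param_pairs$n_fib[p] - param_pairs$n_fib[p - 1]
    window <- ifd_window("INTERRELATED", param_pairs$n_fib[p])
    # blobs removed now (highest indices) never return
    if (d_fib < 0) {
      keep <- seq_len(nrow(cur$fib_upper) + d_fib)
      cur$fib_upper <- cur$fib_upper[keep, , drop = FALSE]
      cur$fib_lower <- cur$fib_lower[keep, , drop = FALSE]
    }
    geom <- NULL
    for (retry in seq_len(max_retries)) {
      cand <- cur
      if (d_myo > 0) {
        cand$myo_upper <- add_blobs(cand$myo_upper, stack, d_myo,
                                    base_geometry$blobs$myo_upper$radius[1],
                                    "MYOCARDIAL", cand$myo_upper$host_layer[1])
        cand$myo_lower <- add_blobs(cand$myo_lower, stack, d_myo,
                                    base_geometry$blobs$myo_lower$radius[1],
                                    "MYOCARDIAL", cand$myo_lower$host_layer[1])
      }
      if (d_fib > 0) {
        cand$fib_upper <- add_blobs(cand$fib_upper, stack, d_fib,
                                    base_geometry$blobs$fib_upper$radius[1],
                                    "FIBROTIC", cand$fib_upper$host_layer[1])
        cand$fib_lower <- add_blobs(cand$fib_lower, stack, d_fib,
                                    base_geometry$blobs$fib_lower$radius[1],
                                    "FIBROTIC", cand$fib_lower$host_layer[1])
      }
      if (retry > max_retries / 2) {
        # fallback: also redraw the non-core fibrotic blobs
        for (nm in c("fib_upper", "fib_lower")) {
          free <- setdiff(seq_len(nrow(cand[[nm]])), seq_len(core_fib))
          for (b in free) {
            pos <- sample_blob_position(stack, cand[[nm]]$radius[b])
            cand[[nm]]$x[b] <- pos[1]
            cand[[nm]]$y[b] <- pos[2]
          }
        }
      }
      iso_up <- rasterize_blobs(cand$myo_upper, stack)
      iso_lo <- rasterize_blobs(cand$myo_lower, stack)
      cand$fib_upper <- enforce_projection_constraint(cand$fib_upper, iso_up, stack)
      cand$fib_lower <- enforce_projection_constraint(cand$fib_lower, iso_lo, stack)
      g <- build_geometry_from_blobs(stack, cand$myo_upper, cand$myo_lower,
                                     cand$fib_upper, cand$fib_lower,
                                     seed = seed)
      if (g$ifd >= window[1] && g$ifd <= window[2]) {
        geom <- g
        cur <- cand
        break
      }
    }
    if (is.null(geom)) {
      stop("interrelated member ", p, " (", param_pairs$n_myo[p], ", ",
           param_pairs$n_fib[p], "): IFD window [", window[1], ", ",
           window[2], "] % not reached in ", max_retries, " local resamples",
           call. = FALSE)
    }
    geom$group_kind <- "INTERRELATED"
    geom$n_myo <- param_pairs$n_myo[p]
    geom$n_fib <- param_pairs$n_fib[p]
    series[[p]] <- geom
  }
  series
}
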