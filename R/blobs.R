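#' Sample a spatially balanced set of cylindrical blobs
#'
#' Blob centers are drawn uniformly over the slab footprint, then the whole
#' set is resampled until a spatial-balance criterion holds, so that patches
#' neither gather in the middle nor scatter on the edge.  The criterion is:
#' (a) every center at least `radius/2` from the footprint edge, (b) the
#' centroid of the centers within `centroid_tol_mm` of the slab center, and
#' (c) the RMS distance of centers from the slab center within +/-20% of its
#' expectation under the uniform law on the admissible box.  A single blob
#' is trivially balanced (only the edge margin applies).
#'
#' @param stack an `fs_layer_stack` (defines the footprint).
#' @param count number of blobs.
#' @param radius_mm blob radius in mm (2.5 for myocardial blobs in isolation
#'   layers, 2.6 for fibrotic blobs in fibrotic layers).
#' @param kind `"MYOCARDIAL"` or `"FIBROTIC"`.
#' @param host_layer slice index the blobs live on (bookkeeping only).
#' @param balance list of balance parameters: `centroid_tol_mm`,
#'   `dispersion_band` (relative band on RMS radius), `max_proposals`.
#' @return data.frame with columns `x`, `y`, `radius`, `kind`, `host_layer`.
#' @export
sample_blob_set <- function(stack, count, radius_mm,
                            kind = c("FIBROTIC", "MYOCARDIAL"),
                            host_layer = NA_integer_,
                            balance = balance_params(stack)) {
  kind <- match.arg(kind)
  stopifnot(count >= 1, radius_mm > 0)
  Lx <- stack$nx * stack$element_size
  Ly <- stack$ny * stack$element_size
  m <- radius_mm / 2
  if (Lx <= 2 * m || Ly <= 2 * m) {
    stop("footprint too small for blobs of radius ", radius_mm, " mm",
         call. = FALSE)
  }
  for (k in seq_len(balance$max_proposals)) {
    x <- runif(count, m, Lx - m)
    y <- runif(count, m, Ly - m)
    if (blob_set_balanced(x, y, Lx, Ly, m, balance)) {
      return(data.frame(x = x, y = y, radius = radius_mm, kind = kind,
                        host_layer = host_layer, stringsAsFactors = FALSE))
    }
  }
  stop("no balanced blob set of ", count, " blobs found within ",
       balance$max_proposals, " proposals; widen the balance tolerances",
       call. = FALSE)
}

#' Default spatial-balance parameters for a footprint
#'
#' The centroid tolerance is 4 mm on the 40 mm footprint and scales
#' proportionally for other footprints.
#' @param stack an `fs_layer_stack`.
#' @param max_proposals proposal budget for resampling.
#' @export
balance_params <- function(stack, max_proposals = 10000L) {
  L <- min(stack$nx, stack$ny) * stack$element_size
  list(centroid_tol_mm = 4 * L / 40,
       dispersion_band = 0.2,
       max_proposals = as.integer(max_proposals))
}

blob_set_balanced <- function(x, y, Lx, Ly, margin, balance) {
  if (length(x) < 2) return(TRUE)
  cx <- Lx / 2; cy <- Ly / 2
  if (sqrt((mean(x) - cx)^2 + (mean(y) - cy)^2) > balance$centroid_tol_mm)
    return(FALSE)
  msq <- mean((x - cx)^2 + (y - cy)^2)
  # E[d^2] for uniform centers on the admissible box
  expected <- ((Lx - 2 * margin)^2 + (Ly - 2 * margin)^2) / 12
  rel <- sqrt(msq / expected)
  rel >= 1 - balance$dispersion_band && rel <= 1 + balance$dispersion_band
}

#' Rasterize a blob set onto the in-plane element grid
#'
#' An element belongs to the mask iff its in-plane center lies within the
#' radius of at least one blob center (union over blobs).
#'
#' @param blobs data.frame as from [sample_blob_set()]; may have zero rows.
#' @param stack an `fs_layer_stack`.
#' @return logical `nx` by `ny` matrix.
#' @export
rasterize_blobs <- function(blobs, stack) {
  ec <- element_centers(stack)
  mask <- matrix(FALSE, stack$nx, stack$ny)
  if (is.null(blobs) || nrow(blobs) == 0) return(mask)
  for (b in seq_len(nrow(blobs))) {
    dx2 <- (ec$x - blobs$x[b])^2
    dy2 <- (ec$y - blobs$y[b])^2
    mask <- mask | (outer(dx2, dy2, `+`) <= blobs$radius[b]^2)
  }
  mask
}

#' Resample fibrotic blobs that obstruct myocardial patches
#'
#' Every myocardial patch in an isolation layer must remain a viable
#' transmural conduction route: the rasterization of the adjacent fibrotic
#' layer's blob set may not intersect the in-plane projection of the
#' isolation layer's myocardial mask.  Offending blobs are resampled
#' (uniformly on the admissible box) until the intersection is empty.
#'
#' @param fibrotic_blobs data.frame of fibrotic blobs.
#' @param isolation_mask logical matrix, the adjacent isolation layer's
#'   myocardial mask.
#' @param stack an `fs_layer_stack`.
#' @param max_proposals resampling budget per offending blob draw.
#' @return the blob data.frame with offending rows replaced.
#' @export
enforce_projection_constraint <- function(fibrotic_blobs, isolation_mask,
                                          stack, max_proposals = 10000L) {
  if (!any(isolation_mask) || nrow(fibrotic_blobs) == 0) return(fibrotic_blobs)
  ec <- element_centers(stack)
  idx <- which(isolation_mask, arr.ind = TRUE)
  myo_x <- ec$x[idx[, 1]]
  myo_y <- ec$y[idx[, 2]]
  Lx <- stack$nx * stack$element_size
  Ly <- stack$ny * stack$element_size
  blob_clear <- function(bx, by, r) {
    all((myo_x - bx)^2 + (myo_y - by)^2 > r^2)
  }
  for (b in seq_len(nrow(fibrotic_blobs))) {
    r <- fibrotic_blobs$radius[b]
    m <- r / 2
    if (blob_clear(fibrotic_blobs$x[b], fibrotic_blobs$y[b], r)) next
    ok <- FALSE
    for (k in seq_len(max_proposals)) {
      px <- runif(1, m, Lx - m)
      py <- runif(1, m, Ly - m)
      if (blob_clear(px, py, r)) {
        fibrotic_blobs$x[b] <- px
        fibrotic_blobs$y[b] <- py
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("projection constraint unsatisfiable: no clear position for ",
           "fibrotic blob ", b, " within ", max_proposals, " proposals ",
           "(myocardial patches cover ", round(100 * mean(isolation_mask), 1),
           "% of the footprint)", call. = FALSE)
    }
  }
  fibrotic_blobs
}

#' Thin fibrotic layer mask from the two thick-layer masks
#'
#' The thin fibrotic layer carries fibrotic tissue exactly where the
#' fibrotic patches of the two thick fibrotic layers overlap in-plane.
#'
#' @param thick_mask_upper,thick_mask_lower logical matrices of equal shape.
#' @return logical matrix, the element-wise intersection.
#' @export
derive_thin_fibrotic_mask <- function(thick_mask_upper, thick_mask_lower) {
  if (!identical(dim(thick_mask_upper), dim(thick_mask_lower))) {
    stop("thick-layer masks have different shapes", call. = FALSE)
  }
  thick_mask_upper & thick_mask_lower
}

#' Connected components (patches) of an in-plane mask
#'
#' A patch is a maximal 8-connected component of TRUE elements; this is how
#' overlapping blob unions become discrete "patches".
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 outside the mask, patch id
#'   (1, 2, ...) inside.
#' @export
label_patches <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  nlab <- 0L
  off <- cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((cur - 1L) %% nx) + 1L
      j <- ((cur - 1L) %/% nx) + 1L
      ni <- i + off[, 1]; nj <- j + off[, 2]
      keep <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
      nb <- (nj[keep] - 1L) * nx + ni[keep]
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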