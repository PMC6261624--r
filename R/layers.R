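#' Build the canonical seven-layer transmural stack
#'
#' The slab wall is discretized into nine element slices spanning seven
#' tissue layers: endocardium (1 slice), isolation layer (1), thick fibrotic
#' layer (2), thin fibrotic layer (1), thick fibrotic layer (2), isolation
#' layer (1), epicardium (1).  With 0.4 mm elements this is the 3.6 mm
#' atrial wall; in-plane dimensions are free as long as they are divisible
#' by the element size.
#'
#' @param dims_mm numeric length-3, slab dimensions (x, y, z) in mm.
#' @param element_size_mm edge length of the cubic elements in mm.
#' @return An object of class `fs_layer_stack` with fields `nx`, `ny`,
#'   `element_size`, and `slices` (a data.frame of `kind`, `layer_id`).
#' @examples
#' st <- build_layer_stack(c(40, 40, 3.6), 0.4)
#' st$nx * st$ny * nrow(st$slices)  # 90000 elements
#' @export
build_layer_stack <- function(dims_mm = c(40, 40, 3.6), element_size_mm = 0.4) {
  stopifnot(length(dims_mm) == 3, all(dims_mm > 0), element_size_mm > 0)
  h <- element_size_mm
  n <- dims_mm / h
  if (any(abs(n - round(n)) > 1e-9)) {
    stop("slab dimensions ", paste(dims_mm, collapse = " x "),
         " mm are not divisible by the element size ", h, " mm",
         call. = FALSE)
  }
  n <- as.integer(round(n))
  # one slice per 0.4 mm-equivalent layer unit; thick fibrotic layers are 2h
  slice_kinds <- c("ENDO", "ISOLATION", "THICK_FIBROTIC", "THICK_FIBROTIC",
                   "THIN_FIBROTIC", "THICK_FIBROTIC", "THICK_FIBROTIC",
                   "ISOLATION", "EPI")
  layer_ids <- c(1L, 2L, 3L, 3L, 4L, 5L, 5L, 6L, 7L)
  if (n[3] != length(slice_kinds)) {
    stop("wall thickness ", dims_mm[3], " mm cannot honor the canonical ",
         "7-layer stack (needs ", length(slice_kinds), " slices of ", h,
         " mm = ", length(slice_kinds) * h, " mm)", call. = FALSE)
  }
  structure(
    list(nx = n[1], ny = n[2], element_size = h,
         slices = data.frame(kind = slice_kinds, layer_id = layer_ids,
                             stringsAsFactors = FALSE)),
    class = "fs_layer_stack")
}

#' @export
print.fs_layer_stack <- function(x, ...) {
  cat("<fs_layer_stack> ", x$nx, " x ", x$ny, " x ", nrow(x$slices),
      " elements (", x$element_size, " mm), ",
      x$nx * x$ny * nrow(x$slices), " total\n", sep = "")
  cat("  slices:", paste(x$slices$kind, collapse = " | "), "\n")
  invisible(x)
}

# Slice indices (1-based, endo at slice 1) for each structural role.
slice_index <- function(stack, what = c("ENDO", "EPI", "ISO_UPPER", "ISO_LOWER",
                                        "THICK_UPPER", "THICK_LOWER", "THIN",
                                        "FIBROTIC_ALL", "ISO_ALL")) {
  what <- match.arg(what)
  k <- stack$slices$kind
  iso <- which(k == "ISOLATION")
  thick <- which(k == "THICK_FIBROTIC")
  switch(what,
    ENDO = which(k == "ENDO"),
    EPI = which(k == "EPI"),
    ISO_UPPER = iso[1], ISO_LOWER = iso[2],
    THICK_UPPER = thick[thick < which(k == "THIN_FIBROTIC")],
    THICK_LOWER = thick[thick > which(k == "THIN_FIBROTIC")],
    THIN = which(k == "THIN_FIBROTIC"),
    FIBROTIC_ALL = which(k %in% c("THICK_FIBROTIC", "THIN_FIBROTIC")),
    ISO_ALL = iso)
}

# In-plane element center coordinates (mm); element (i, j) has center
# ((i - 0.5) h, (j - 0.5) h) with 1-based indices.
element_centers <- function(stack) {
  h <- stack$element_size
  list(x = (seq_len(stack$nx) - 0.5) * h,
       y = (seq_len(stack$ny) - 0.5) * h)
}
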