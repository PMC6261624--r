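#' Save / load geometries and simulation results
#'
#' Runtime persistence uses R serialization (`.rds`); alongside a geometry,
#' a plain-text JSON sidecar with the metadata (seed, group, counts,
#' realized IFD/EDD) is written so runs remain auditable without R.
#'
#' @param geometry an `fs_slab_geometry`.
#' @param path output path (`.rds`).
#' @return invisibly, `path`.
#' @export
save_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "fs_slab_geometry"))
  saveRDS(geometry, path)
  meta <- list(seed = geometry$seed, group = geometry$group_kind,
               n_myo = geometry$n_myo, n_fib = geometry$n_fib,
               ifd = geometry$ifd, edd = geometry$edd,
               nx = geometry$stack$nx, ny = geometry$stack$ny,
               n_slices = nrow(geometry$stack$slices),
               element_size_mm = geometry$stack$element_size)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_geometry
#' @export
load_geometry <- function(path) {
  g <- readRDS(path)
  stopifnot(inherits(g, "fs_slab_geometry"))
  g
}

#' @rdname save_geometry
#' @param result an `fs_simulation_result`.
#' @export
save_result <- function(result, path) {
  stopifnot(inherits(result, "fs_simulation_result"))
  saveRDS(result, path)
  invisible(path)
}

#' @rdname save_geometry
#' @export
load_result <- function(path) {
  r <- readRDS(path)
  stopifnot(inherits(r, "fs_simulation_result"))
  r
}

#' Export electrogram signals as CSV
#'
#' @param signals matrix (time x sites) as from [electrogram_signals()], or
#'   a single numeric signal.
#' @param path output CSV path.
#' @param fs sampling rate (Hz).
#' @export
export_signals_csv <- function(signals, path, fs = 1000) {
  signals <- cbind(signals)
  df <- data.frame(time_s = (seq_len(nrow(signals)) - 1) / fs, signals)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
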