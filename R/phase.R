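wrap_phase <- function(x) {
  # wrap to (-pi, pi]
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Phase field of a voltage movie
#'
#' Per-element activation phase
#' `theta(t) = atan2(V(t + tau) - Vmean, V(t) - Vmean)` with `Vmean` the
#' per-element temporal mean over the whole record and a delay `tau` of
#' 30 ms.  The phase is defined for `t <= T - tau`; samples where both
#' arguments vanish are marked undefined (`NA`) and excluded from
#' singularity detection.
#'
#' @param sheet voltage array `nx` x `ny` x frames (mV), e.g. from
#'   [movie_sheet()].
#' @param tau_ms delay in ms (sampling is 1 kHz, so 1 frame = 1 ms).
#' @return list of class `fs_phase_field`: `theta` (`nx` x `ny` x
#'   `T - tau`), `vmean`, `tau_ms`.
#' @export
compute_phase <- function(sheet, tau_ms = 30) {
  stopifnot(length(dim(sheet)) == 3)
  Tn <- dim(sheet)[3]
  tau <- as.integer(tau_ms)
  if (Tn <= tau) stop("record (", Tn, " frames) not longer than tau (",
                      tau, " ms)", call. = FALSE)
  vmean <- apply(sheet, c(1, 2), mean)
  nt <- Tn - tau
  a <- sheet[, , (tau + 1):Tn, drop = FALSE] - as.vector(vmean)
  b <- sheet[, , 1:nt, drop = FALSE] - as.vector(vmean)
  theta <- atan2(a, b)
  theta[a == 0 & b == 0] <- NA_real_
  structure(list(theta = theta, vmean = vmean, tau_ms = tau_ms),
            class = "fs_phase_field")
}

#' Detect phase singularities in one phase frame
#'
#' Topological-charge detection on elementary 2 x 2 element loops: the sum
#' of wrapped phase differences around a loop equals +/- 2 pi exactly at a
#' singularity and 0 elsewhere.  The reported position is the loop center,
#' in mm; chirality is the winding sign.
#'
#' @param phase_frame `nx` x `ny` phase matrix (radians).
#' @param element_size_mm element edge length.
#' @return data.frame with columns `x`, `y` (mm), `chirality`.
#' @export
detect_phase_singularities <- function(phase_frame, element_size_mm = 0.4) {
  nx <- nrow(phase_frame); ny <- ncol(phase_frame)
  p00 <- phase_frame[-nx, -ny, drop = FALSE]
  p10 <- phase_frame[-1, -ny, drop = FALSE]
  p11 <- phase_frame[-1, -1, drop = FALSE]
  p01 <- phase_frame[-nx, -1, drop = FALSE]
  s <- wrap_phase(p10 - p00) + wrap_phase(p11 - p10) +
       wrap_phase(p01 - p11) + wrap_phase(p00 - p01)
  hit <- which(!is.na(s) & abs(s) > pi, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(x = numeric(0), y = numeric(0), chirality = integer(0)))
  }
  data.frame(x = hit[, 1] * element_size_mm,
             y = hit[, 2] * element_size_mm,
             chirality = as.integer(sign(s[hit])))
}

#' Detect phase singularities in every frame of a phase field
#'
#' @param phase an `fs_phase_field`.
#' @param element_size_mm element edge length (mm).
#' @return list of per-frame data.frames (see
#'   [detect_phase_singularities()]).
#' @export
detect_ps_frames <- function(phase, element_size_mm = 0.4) {
  nt <- dim(phase$theta)[3]
  lapply(seq_len(nt), function(t) {
    detect_phase_singularities(phase$theta[, , t], element_size_mm)
  })
}

#' Track phase singularities across frames
#'
#' Greedy nearest-neighbor linkage: a singularity at frame `t + 1` is
#' appended to the track whose last position (at frame `t`) is nearest and
#' closer than the gate (1 mm, the distance a tip moving below 1 m/s can
#' cover in 1 ms).  Nearest distance wins; exact ties go to the older
#' (lower-id) track.  Unmatched detections open new tracks; unmatched
#' tracks close.
#'
#' @param ps_frames list of per-frame detection data.frames (1 ms spacing).
#' @param gate_mm linkage gate (mm per frame).
#' @return data.frame with one row per track: `id`, `birth`, `death`
#'   (frame indices), `lifespan_ms`, `chirality`, and list-columns `x`,
#'   `y` of per-frame positions.
#' @export
track_singularities <- function(ps_frames, gate_mm = 1) {
  tracks <- list()   # each: list(x, y, chirality, birth, last_frame, open)
  open_ids <- integer(0)
  for (t in seq_along(ps_frames)) {
    det <- ps_frames[[t]]
    n_det <- nrow(det)
    assigned_det <- rep(FALSE, n_det)
    if (length(open_ids) && n_det) {
      last_x <- vapply(tracks[open_ids], function(tr) tr$x[length(tr$x)], 0)
      last_y <- vapply(tracks[open_ids], function(tr) tr$y[length(tr$y)], 0)
      d <- sqrt(outer(last_x, det$x, `-`)^2 + outer(last_y, det$y, `-`)^2)
      cand <- which(d < gate_mm, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], open_ids[cand[, 1]])
        used_tr <- rep(FALSE, length(open_ids))
        for (ci in ord) {
          tr_i <- cand[ci, 1]; de_i <- cand[ci, 2]
          if (used_tr[tr_i] || assigned_det[de_i]) next
          used_tr[tr_i] <- TRUE
          assigned_det[de_i] <- TRUE
          id <- open_ids[tr_i]
          tracks[[id]]$x <- c(tracks[[id]]$x, det$x[de_i])
          tracks[[id]]$y <- c(tracks[[id]]$y, det$y[de_i])
          tracks[[id]]$last_frame <- t
        }
      }
    }
    # close unmatched tracks
    open_ids <- open_ids[vapply(tracks[open_ids],
                                function(tr) tr$last_frame == t, TRUE)]
    # open new tracks for unmatched detections
    for (de_i in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- list(x = det$x[de_i], y = det$y[de_i],
                                           chirality = det$chirality[de_i],
                                           birth = t, last_frame = t)
      open_ids <- c(open_ids, length(tracks))
    }
  }
  if (!length(tracks)) {
    return(data.frame(id = integer(0), birth = integer(0), death = integer(0),
                      lifespan_ms = numeric(0), chirality = integer(0)))
  }
  out <- data.frame(
    id = seq_along(tracks),
    birth = vapply(tracks, `[[`, 0L, "birth"),
    death = vapply(tracks, `[[`, 0L, "last_frame"),
    chirality = vapply(tracks, function(tr) as.integer(tr$chirality), 0L))
  out$lifespan_ms <- pmax(out$death - out$birth, 1)
  out$x <- I(lapply(tracks, `[[`, "x"))
  out$y <- I(lapply(tracks, `[[`, "y"))
  out
}

#' Summary statistics of phase-singularity tracks
#'
#' @param tracks data.frame from [track_singularities()].
#' @param duration_s analysed record duration in seconds.
#' @param n_frames number of phase frames (for the count series); inferred
#'   from the tracks when omitted.
#' @return list of class `fs_ps_statistics`: `n_tracks`, `mean_lifespan_ms`,
#'   `generation_rate_per_s` (tracks per second of record),
#'   `count_series` (singularities present in each 1 ms frame),
#'   `mean_count_first_500ms`, `mean_count`.
#' @export
ps_statistics <- function(tracks, duration_s, n_frames = NULL) {
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  if (is.null(n_frames)) {
    n_frames <- if (nrow(tracks)) max(tracks$death) else 0L
  }
  counts <- integer(n_frames)
  for (i in seq_len(nrow(tracks))) {
    fr <- tracks$birth[i]:tracks$death[i]
    counts[fr] <- counts[fr] + 1L
  }
  structure(list(
    n_tracks = nrow(tracks),
    mean_lifespan_ms = if (nrow(tracks)) mean(tracks$lifespan_ms) else NA_real_,
    generation_rate_per_s = nrow(tracks) / duration_s,
    count_series = counts,
    mean_count_first_500ms = if (n_frames) mean(counts[seq_len(min(500, n_frames))]) else NA_real_,
    mean_count = if (n_frames) mean(counts) else NA_real_),
    class = "fs_ps_statistics")
}

#' Stability classification of a simulation
#'
#' A simulation maintains AF when chaotic activity persists strictly longer
#' than the stability threshold (10 s at paper scale; the desk-scale preset
#' scales the threshold with its shortened maximal time).
#'
#' @param result an `fs_simulation_result`, or a duration in seconds.
#' @param threshold_s stability threshold (s).
#' @return `"STABLE"` or `"NON_STABLE"`.
#' @export
classify_stability <- function(result, threshold_s = NULL) {
  duration <- if (inherits(result, "fs_simulation_result")) {
    if (is.null(threshold_s)) threshold_s <- result$config$stability_threshold_s
    result$duration_s
  } else {
    as.numeric(result)
  }
  if (is.null(threshold_s)) threshold_s <- 10
  if (duration > threshold_s) "STABLE" else "NON_STABLE"
}
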