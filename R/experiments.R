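#' Desk-scale study preset
#'
#' The full study (40 x 40 mm footprint, 10 s maximal time, 65+ runs)
#' needs cluster-level compute.  The desk preset keeps the transmural
#' architecture, element size, cell models and S1-S2 initiation intact but
#' shrinks the footprint, shortens the maximal time, rescales the blob
#' counts and radii by the footprint-area ratio, and scales the stability
#' threshold with the shortened run; results from it are qualitative.
#'
#' The S2 coupling interval must fall inside the vulnerable window of the
#' parameter set in use (it depends on the coupling parameters the
#' reference protocol leaves open); for the default parameters the window
#' center was measured once at 235 ms on both 24 and 40 mm footprints, and
#' the preset uses that value.
#'
#' @param footprint_mm in-plane slab edge (mm), a multiple of 0.4.
#' @param max_time maximal simulated time (s).
#' @return list with `stack`, `solver` (an `fs_solver_config`),
#'   `protocol`, `scale` (area ratio to the 40 mm footprint).
#' @export
desk_preset <- function(footprint_mm = 24, max_time = 1.0) {
  stack <- build_layer_stack(c(footprint_mm, footprint_mm, 3.6), 0.4)
  scale <- (footprint_mm / 40)^2
  cfg <- solver_config(max_time = max_time,
                       stability_threshold_s = 10 * max_time / 10)
  # S2 coupling interval: 235 ms, the measured center of the vulnerable
  # window of this parameter set (verified on 24 and 40 mm footprints)
  s2_time <- 0.235
  dims <- c(stack$nx, stack$ny, nrow(stack$slices))
  list(stack = stack, solver = cfg,
       protocol = s1s2_protocol(dims, s2_time = s2_time),
       scale = scale,
       n_myo_range = pmax(1, round(5:19 * scale)),
       n_fib_scale = scale)
}

#' Run one simulation group end to end
#'
#' Generates geometries per the group protocol, runs the monodomain
#' simulations with S1-S2 initiation, analyses each run (stability, phase
#' singularities on the endocardium, breakthrough counts) and assembles
#' the study table.
#'
#' @param configs list of `fs_group_config` (one per simulation), or a
#'   single config reused with successive seeds.
#' @param n_sims number of simulations when a single config is given.
#' @param seeds integer seeds, one per simulation.
#' @param solver an `fs_solver_config`.
#' @param protocol an `fs_stim_protocol` sized for the geometry mesh.
#' @param analyze compute PS/breakthrough summaries per run.
#' @return data.frame of class `fs_study_table`, one row per simulation:
#'   ids, blob counts, realized IFD/EDD, duration, stability label, PS
#'   statistics and veritable breakthrough counts.
#' @export
run_group <- function(configs, n_sims = NULL, seeds = NULL,
                      solver = solver_config(), protocol = NULL,
                      analyze = TRUE) {
  if (inherits(configs, "fs_group_config")) {
    if (is.null(n_sims)) n_sims <- length(seeds)
    configs <- rep(list(configs), n_sims)
  }
  if (is.null(seeds)) seeds <- seq_along(configs)
  stopifnot(length(seeds) == length(configs))
  rows <- vector("list", length(configs))
  for (s in seq_along(configs)) {
    geom <- generate_geometry(configs[[s]], seed = seeds[s])
    dims <- c(geom$stack$nx, geom$stack$ny, nrow(geom$stack$slices))
    prot <- if (is.null(protocol)) s1s2_protocol(dims) else protocol
    sim <- run_simulation(geom, prot, solver)
    row <- data.frame(
      sim_id = s, group = geom$group_kind, seed = seeds[s],
      n_myo = geom$n_myo, n_fib = geom$n_fib,
      ifd = geom$ifd, edd = geom$edd,
      duration_s = sim$duration_s,
      stability = classify_stability(sim),
      censored = sim$termination == "max_time")
    if (analyze) {
      endo <- movie_sheet(sim, "endo")
      if (dim(endo)[3] > 40) {
        ph <- compute_phase(endo)
        tracks <- track_singularities(
          detect_ps_frames(ph, geom$stack$element_size))
        st <- ps_statistics(tracks, sim$duration_s)
        row$n_ps_tracks <- st$n_tracks
        row$ps_mean_lifespan_ms <- st$mean_lifespan_ms
        row$ps_rate_per_s <- st$generation_rate_per_s
      } else {
        row$n_ps_tracks <- NA_integer_
        row$ps_mean_lifespan_ms <- NA_real_
        row$ps_rate_per_s <- NA_real_
      }
      bt <- detect_breakthroughs(movie_sheet(sim, "epi"), geom, "epi")
      row$n_breakthroughs_epi <- sum(bt$veritable)
    }
    rows[[s]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fs_study_table", class(out))
  out
}

#' Kaplan-Meier estimate of AF episode survival
#'
#' Product-limit estimator of the probability that an AF episode is still
#' active at time t.  Simulations still active at the maximal simulated
#' time are censored.
#'
#' @param durations episode durations (s).
#' @param censored logical; TRUE when the episode outlived the simulation.
#' @return data.frame `time`, `n_risk`, `n_event`, `survival` (the stepped
#'   estimate after each event time).
#' @export
kaplan_meier <- function(durations, censored = rep(FALSE, length(durations))) {
  if (!length(durations)) stop("no durations", call. = FALSE)
  stopifnot(length(censored) == length(durations), all(durations > 0))
  fit <- survival::survfit(
    survival::Surv(durations, !censored) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Compare duration distributions between ranked subsets
#'
#' Ranks the study rows by a structural variable (EDD or IFD), extracts the
#' first and last `k` rows, and compares their episode durations with a
#' two-sample Kolmogorov-Smirnov test and an independent-sample t test
#' (both always computed; ranking ties are broken by simulation id).
#'
#' @param rows an `fs_study_table` (needs `duration_s` and the ranking
#'   variable).
#' @param ranking_var `"edd"` or `"ifd"`.
#' @param k subset size; first/last 28 of the 65 stochastic simulations
#'   (or 20 of the 42 non-stable ones) in the study design.
#' @param non_stable_only restrict to non-stable rows first.
#' @return list of class `fs_subset_comparison` with the subset ids, the
#'   KS and t statistics and p-values, and `significant` (p < 0.05 on the
#'   t test).
#' @export
compare_subsets <- function(rows, ranking_var = c("edd", "ifd"), k = 28,
                            non_stable_only = FALSE) {
  ranking_var <- match.arg(ranking_var)
  if (non_stable_only) rows <- rows[rows$stability == "NON_STABLE", , drop = FALSE]
  if (2 * k > nrow(rows)) {
    stop("subsets of ", k, " overlap: only ", nrow(rows), " rows", call. = FALSE)
  }
  ord <- order(rows[[ranking_var]], rows$sim_id)
  lo <- rows[ord[seq_len(k)], ]
  hi <- rows[ord[seq(nrow(rows) - k + 1, nrow(rows))], ]
  ks <- suppressWarnings(stats::ks.test(lo$duration_s, hi$duration_s))
  tt <- stats::t.test(lo$duration_s, hi$duration_s, var.equal = FALSE)
  structure(list(ranking_var = ranking_var, k = k,
                 low_ids = lo$sim_id, high_ids = hi$sim_id,
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
                 t_statistic = unname(tt$statistic), t_p = tt$p.value,
                 significant = tt$p.value < 0.05),
            class = "fs_subset_comparison")
}

#' @export
print.fs_subset_comparison <- function(x, ...) {
  cat("<fs_subset_comparison> first/last ", x$k, " by ", toupper(x$ranking_var),
      ": KS D = ", round(x$ks_statistic, 3), " (p = ", signif(x$ks_p, 3),
      "), t = ", round(x$t_statistic, 3), " (p = ", signif(x$t_p, 3), ")",
      if (x$significant) " *", "\n", sep = "")
  invisible(x)
}

#' Export study outputs as text files
#'
#' Writes the study table (CSV), the subset comparisons (JSON), the
#' Kaplan-Meier curve (CSV) and the IFD/EDD/duration time-map triplets
#' (CSV) into a directory.
#'
#' @param rows an `fs_study_table`.
#' @param comparisons list of `fs_subset_comparison` (may be empty).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
export_results <- function(rows, comparisons = list(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table = file.path(out_dir, "study_table.csv"),
    comparisons = file.path(out_dir, "comparisons.json"),
    km = file.path(out_dir, "kaplan_meier.csv"),
    timemap = file.path(out_dir, "time_map.csv"))
  utils::write.csv(as.data.frame(rows), paths["table"], row.names = FALSE)
  jsonlite::write_json(lapply(comparisons, unclass), paths["comparisons"],
                       auto_unbox = TRUE, digits = NA)
  km <- kaplan_meier(rows$duration_s, rows$censored)
  utils::write.csv(km, paths["km"], row.names = FALSE)
  utils::write.csv(rows[, c("ifd", "edd", "duration_s")], paths["timemap"],
                   row.names = FALSE)
  invisible(paths)
}
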