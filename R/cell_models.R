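#' Coupled-unit membrane parameters
#'
#' Parameters of one myocyte-fibroblast unit: the Nygren human atrial
#' myocyte electrically loaded by `numf` identical active fibroblasts
#' through a gap-junctional conductance `ggap` per fibroblast.  Defaults:
#' myocyte capacitance 0.05 nF; fibroblast capacitance 6.3 pF and
#' per-fibroblast conductance 0.5 nS as in the published active-fibroblast
#' coupling configuration.  Myocardial tissue carries `numf = 3`, fibrotic
#' tissue `numf = 45`.
#'
#' @param numf fibroblasts coupled to the myocyte.
#' @param ggap gap-junctional conductance per fibroblast (nS).
#' @param cm_myo myocyte membrane capacitance (nF).
#' @param cm_fb fibroblast membrane capacitance (nF).
#' @return named list of class `fs_cell_params`.
#' @export
cell_params <- function(numf = 3, ggap = 0.5, cm_myo = 0.05, cm_fb = 0.0063) {
  stopifnot(numf >= 0, ggap >= 0, cm_myo > 0, cm_fb > 0)
  structure(list(numf = numf, ggap = ggap, cm_myo = cm_myo, cm_fb = cm_fb),
            class = "fs_cell_params")
}

#' Published initial state of the coupled unit
#'
#' The Nygren myocyte initial conditions as published, plus the fibroblast
#' (membrane potential and the two delayed-rectifier gates).
#' @return named numeric vector of 32 states.
#' @export
cell_initial_state <- function() cpp_cell_initial_state()

#' Time derivatives of the full coupled unit
#'
#' Evaluates the right-hand side of the myocyte and fibroblast membrane
#' equations at a state: the myocyte rate is
#' `-(Imyo + Istim + numf * Ggap * (Vmyo - VFb)) / Cm_myo` and the
#' fibroblast rate is `-(IFb + Ggap * (VFb - Vmyo)) / Cm_Fb`; gating and
#' concentration derivatives follow the published model equations.  Rates
#' are per second.
#'
#' @param state named 32-state vector (see [cell_initial_state()]).
#' @param i_stim stimulus current in pA (depolarizing stimuli are negative).
#' @param params an `fs_cell_params`.
#' @return named vector of time derivatives (per second).
#' @export
cell_derivatives <- function(state, i_stim = 0, params = cell_params()) {
  d <- cpp_cell_derivs(as.numeric(state), i_stim, unclass(params))
  if (any(!is.finite(d))) {
    stop("non-finite derivative for state variable(s): ",
         paste(names(d)[!is.finite(d)], collapse = ", "), call. = FALSE)
  }
  d
}

#' Myocyte-only derivatives (reaction part)
#'
#' @inheritParams cell_derivatives
#' @return derivatives of the 29 myocyte states.
#' @export
myocyte_derivatives <- function(state, i_stim = 0, params = cell_params()) {
  cell_derivatives(state, i_stim, params)[1:29]
}

#' Fibroblast derivatives given the myocyte potential
#'
#' @inheritParams cell_derivatives
#' @param v_myo myocyte membrane potential (mV) seen through the gap
#'   junction; defaults to the `V` entry of `state`.
#' @return derivatives of `V_fb`, `r_fb`, `s_fb`.
#' @export
fibroblast_derivatives <- function(state, v_myo = state[["V"]],
                                   params = cell_params()) {
  st <- as.numeric(state)
  st[1] <- v_myo
  cell_derivatives(st, 0, params)[30:32]
}

#' Advance a coupled unit by forward Euler
#'
#' @param state 32-state vector.
#' @param i_stim stimulus current (pA), held constant over the steps.
#' @param dt time step in seconds (10 us default).
#' @param n_steps number of steps.
#' @param params an `fs_cell_params`.
#' @return the updated named state vector.
#' @export
coupled_unit_step <- function(state, i_stim = 0, dt = 1e-5, n_steps = 1,
                              params = cell_params()) {
  r <- cpp_cell_run(as.numeric(state), unclass(params), dt, as.integer(n_steps),
                    0, if (i_stim != 0) n_steps * dt else 0, i_stim, 0,
                    as.integer(n_steps))
  r$state
}

.settle_cache <- new.env(parent = emptyenv())

#' Settled (quiescent) state of a coupled unit
#'
#' Integrates the unstimulated unit for `settle_time` seconds of model time
#' and returns the end state, cached per parameter set.  A warning is
#' raised if the membrane potential still drifts by more than `drift_tol`
#' mV over the final second.
#'
#' @param params an `fs_cell_params`.
#' @param settle_time settling duration in seconds (model time), >= 5.
#' @param dt integration step (s).
#' @param drift_tol drift tolerance (mV per second) for the settled check.
#' @return named 32-state vector.
#' @export
steady_state_init <- function(params = cell_params(), settle_time = 30,
                              dt = 1e-5, drift_tol = 0.02) {
  stopifnot(settle_time >= 5)
  key <- paste(params$numf, params$ggap, params$cm_myo, params$cm_fb,
               settle_time, dt, sep = "|")
  if (!is.null(.settle_cache[[key]])) return(.settle_cache[[key]])
  n <- as.integer(round(settle_time / dt))
  rec <- as.integer(round(0.01 / dt))  # record every 10 ms
  r <- cpp_cell_run(cpp_cell_initial_state(), unclass(params), dt, n,
                    1e9, 0, 0, 0, rec)
  v <- r$V
  drift <- abs(v[length(v)] - v[length(v) - min(100, length(v) - 1)])
  if (drift > drift_tol) {
    warning("membrane potential still drifting ", signif(drift, 3),
            " mV over the final second after ", settle_time, " s of settling",
            call. = FALSE)
  }
  .settle_cache[[key]] <- r$state
  r$state
}

#' Run a single-cell action potential and measure its morphology
#'
#' Stimulates a settled unit with a rectangular current pulse and reports
#' resting potential, peak, amplitude, maximum upstroke velocity and APD90.
#'
#' @param params an `fs_cell_params`.
#' @param stim_amp stimulus amplitude (pA, negative = depolarizing).
#' @param stim_dur stimulus duration (s).
#' @param duration recorded duration after the stimulus onset (s).
#' @param dt integration step (s).
#' @param state optional starting state; defaults to [steady_state_init()].
#' @return list with `time` (s), `V` (mV), `V_fb` and a `metrics` list
#'   (`rest`, `peak`, `amplitude`, `apd90_ms`, `max_dvdt`).
#' @export
single_cell_ap <- function(params = cell_params(), stim_amp = -1500,
                           stim_dur = 0.002, duration = 0.6, dt = 1e-5,
                           state = NULL) {
  if (is.null(state)) state <- steady_state_init(params)
  onset <- 0.005
  n <- as.integer(round((duration + onset) / dt))
  r <- cpp_cell_run(as.numeric(state), unclass(params), dt, n,
                    onset, stim_dur, stim_amp, 0, 10L)
  v <- r$V; t <- r$time
  rest <- v[1]
  peak_i <- which.max(v)
  peak <- v[peak_i]
  v90 <- peak - 0.9 * (peak - rest)
  below <- which(v[(peak_i + 1):length(v)] < v90)
  apd90 <- if (length(below)) (t[peak_i + below[1]] - (onset + stim_dur)) * 1000 else NA_real_
  list(time = t, V = v, V_fb = r$V_fb, state = r$state,
       metrics = list(rest = rest, peak = peak, amplitude = peak - rest,
                      apd90_ms = apd90,
                      max_dvdt = max(diff(v) / diff(t)) / 1000))
}
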