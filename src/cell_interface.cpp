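#include <Rcpp.h>
#include "cellmodel.h"
using namespace Rcpp;

static CellParams params_from_list(const List &p) {
  CellParams cp;
  cp.numf = as<double>(p["numf"]);
  cp.ggap = as<double>(p["ggap"]);
  cp.cm_myo = as<double>(p["cm_myo"]);
  cp.cm_fb = as<double>(p["cm_fb"]);
  return cp;
}

static CharacterVector state_names() {
  return CharacterVector::create(
      "V", "Na_c", "K_c", "Ca_c", "Na_i", "K_i", "Ca_i", "Ca_d",
      "m", "h1", "h2", "d_L", "f_L1", "f_L2", "r", "s",
      "r_sus", "s_sus", "n", "p_a", "F1", "F2", "Ca_up", "Ca_rel",
      "O_C", "O_TC", "O_TMgC", "O_TMgMg", "O_Calse",
      "V_fb", "r_fb", "s_fb");
}

// [[Rcpp::export]]
NumericVector cpp_cell_initial_state() {
  NumericVector y(FS_NSTATE);
  fs_cell_initial(&y[0]);
  y.attr("names") = state_names();
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_cell_derivs(NumericVector state, double i_stim, List params) {
  if (state.size() != FS_NSTATE) stop("state must have %d entries", FS_NSTATE);
  CellParams cp = params_from_list(params);
  NumericVector dy(FS_NSTATE);
  fs_cell_derivs(&state[0], &dy[0], i_stim, cp);
  dy.attr("names") = state_names();
  return dy;
}

// Forward-Euler integration of a single coupled unit.  Stimulus current
// i_stim_amp (pA) is applied on [stim_onset, stim_onset + stim_dur) seconds,
// repeated every stim_period seconds if stim_period > 0.  Voltages are
// recorded every record_every steps.
// [[Rcpp::export]]
List cpp_cell_run(NumericVector state, List params, double dt, int n_steps,
                  double stim_onset, double stim_dur, double stim_amp,
                  double stim_period, int record_every) {
  if (state.size() != FS_NSTATE) stop("state must have %d entries", FS_NSTATE);
  CellParams cp = params_from_list(params);
  std::vector<double> y(state.begin(), state.end());
  int n_rec = n_steps / record_every + 1;
  NumericVector t_out(n_rec), v_out(n_rec), vfb_out(n_rec);
  int rec = 0;
  t_out[rec] = 0.0; v_out[rec] = y[IDX_V]; vfb_out[rec] = y[IDX_VFB]; ++rec;
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    double tt = t - stim_onset;
    if (stim_period > 0.0 && tt >= 0.0) {
      tt -= std::floor(tt / stim_period) * stim_period;
    }
    double istim = (tt >= 0.0 && tt < stim_dur) ? stim_amp : 0.0;
    if (fs_cell_euler(&y[0], istim, cp, dt)) {
      stop("non-finite state at t = %g s", t);
    }
    if ((s + 1) % record_every == 0 && rec < n_rec) {
      t_out[rec] = (s + 1) * dt; v_out[rec] = y[IDX_V];
      vfb_out[rec] = y[IDX_VFB]; ++rec;
    }
  }
  NumericVector fin(y.begin(), y.end());
  fin.attr("names") = state_names();
  return List::create(_["time"] = t_out, _["V"] = v_out, _["V_fb"] = vfb_out,
                      _["state"] = fin);
}
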