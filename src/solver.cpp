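// Monodomain tissue stepper: per-element coupled-unit reaction (forward
// Euler, 10 us default) followed by an implicit diffusion sub-step solved
// by Jacobi-preconditioned conjugate gradients on the element-centered
// stiffness operator.  Elements with zero conductivity have empty operator
// rows and are untouched by diffusion (internal zero-flux barriers).
#include <Rcpp.h>
#include "cellmodel.h"
using namespace Rcpp;

namespace {

struct CSC {
  const int *p, *i;
  const double *x;
  int n;
};

inline void csc_mul(const CSC &A, const double *v, double *out) {
  for (int c = 0; c < A.n; ++c) out[c] = 0.0;
  for (int c = 0; c < A.n; ++c) {
    double vc = v[c];
    for (int k = A.p[c]; k < A.p[c + 1]; ++k) out[A.i[k]] += A.x[k] * vc;
  }
}

// Symmetric half-storage form of a CSC matrix: diagonal plus strictly
// upper entries, for a cheaper repeated matvec inside the time loop.
struct SymA {
  int n;
  std::vector<double> diag;
  std::vector<int> up_p;    // per-column pointers into ui/ux (upper part)
  std::vector<int> ui;      // row indices (i < c)
  std::vector<double> ux;
};

SymA build_sym(const CSC &A) {
  SymA s;
  s.n = A.n;
  s.diag.assign(A.n, 0.0);
  s.up_p.assign(A.n + 1, 0);
  for (int c = 0; c < A.n; ++c) {
    for (int k = A.p[c]; k < A.p[c + 1]; ++k) {
      if (A.i[k] == c) s.diag[c] = A.x[k];
      else if (A.i[k] < c) ++s.up_p[c + 1];
    }
  }
  for (int c = 0; c < A.n; ++c) s.up_p[c + 1] += s.up_p[c];
  s.ui.resize(s.up_p[A.n]);
  s.ux.resize(s.up_p[A.n]);
  std::vector<int> pos(s.up_p.begin(), s.up_p.end() - 1);
  for (int c = 0; c < A.n; ++c) {
    for (int k = A.p[c]; k < A.p[c + 1]; ++k) {
      if (A.i[k] < c) {
        s.ui[pos[c]] = A.i[k];
        s.ux[pos[c]] = A.x[k];
        ++pos[c];
      }
    }
  }
  return s;
}

inline void sym_mul(const SymA &A, const double *v, double *out) {
  for (int c = 0; c < A.n; ++c) out[c] = A.diag[c] * v[c];
  for (int c = 0; c < A.n; ++c) {
    const double vc = v[c];
    double acc = 0.0;
    for (int k = A.up_p[c]; k < A.up_p[c + 1]; ++k) {
      const int i = A.ui[k];
      const double x = A.ux[k];
      out[i] += x * vc;
      acc += x * v[i];
    }
    out[c] += acc;
  }
}

// PCG on the symmetric half-storage operator.
int pcg_sym(const SymA &A, const double *b, double *x, const double *dinv,
            double tol, int maxit, std::vector<double> &r,
            std::vector<double> &z, std::vector<double> &q,
            std::vector<double> &p_) {
  int n = A.n;
  double bnorm = 0.0;
  for (int j = 0; j < n; ++j) bnorm += b[j] * b[j];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    for (int j = 0; j < n; ++j) x[j] = 0.0;
    return 0;
  }
  sym_mul(A, x, q.data());
  double rnorm0 = 0.0;
  for (int j = 0; j < n; ++j) {
    r[j] = b[j] - q[j];
    rnorm0 += r[j] * r[j];
  }
  if (std::sqrt(rnorm0) <= tol * bnorm) return 0;
  double rz = 0.0;
  for (int j = 0; j < n; ++j) {
    z[j] = dinv[j] * r[j];
    p_[j] = z[j];
    rz += r[j] * z[j];
  }
  for (int it = 1; it <= maxit; ++it) {
    sym_mul(A, p_.data(), q.data());
    double pq = 0.0;
    for (int j = 0; j < n; ++j) pq += p_[j] * q[j];
    if (pq == 0.0) return it;
    double alpha = rz / pq;
    double rnorm = 0.0;
    for (int j = 0; j < n; ++j) {
      x[j] += alpha * p_[j];
      r[j] -= alpha * q[j];
      rnorm += r[j] * r[j];
    }
    if (std::sqrt(rnorm) <= tol * bnorm) return it;
    double rz_new = 0.0;
    for (int j = 0; j < n; ++j) {
      z[j] = dinv[j] * r[j];
      rz_new += r[j] * z[j];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int j = 0; j < n; ++j) p_[j] = z[j] + beta * p_[j];
  }
  return -1;
}

// PCG with diagonal preconditioner; returns iterations used, -1 on failure.
int pcg(const CSC &A, const double *b, double *x, const double *dinv,
        double tol, int maxit, std::vector<double> &r, std::vector<double> &z,
        std::vector<double> &q) {
  int n = A.n;
  double bnorm = 0.0;
  for (int j = 0; j < n; ++j) bnorm += b[j] * b[j];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    for (int j = 0; j < n; ++j) x[j] = 0.0;
    return 0;
  }
  csc_mul(A, x, q.data());
  double rnorm0 = 0.0;
  for (int j = 0; j < n; ++j) {
    r[j] = b[j] - q[j];
    rnorm0 += r[j] * r[j];
  }
  if (std::sqrt(rnorm0) <= tol * bnorm) return 0;
  std::vector<double> p_(n);
  double rz = 0.0;
  for (int j = 0; j < n; ++j) {
    z[j] = dinv[j] * r[j];
    p_[j] = z[j];
    rz += r[j] * z[j];
  }
  for (int it = 1; it <= maxit; ++it) {
    csc_mul(A, p_.data(), q.data());
    double pq = 0.0;
    for (int j = 0; j < n; ++j) pq += p_[j] * q[j];
    if (pq == 0.0) return it;  // exact solution reached
    double alpha = rz / pq;
    double rnorm = 0.0;
    for (int j = 0; j < n; ++j) {
      x[j] += alpha * p_[j];
      r[j] -= alpha * q[j];
      rnorm += r[j] * r[j];
    }
    if (std::sqrt(rnorm) <= tol * bnorm) return it;
    double rz_new = 0.0;
    for (int j = 0; j < n; ++j) {
      z[j] = dinv[j] * r[j];
      rz_new += r[j] * z[j];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int j = 0; j < n; ++j) p_[j] = z[j] + beta * p_[j];
  }
  return -1;
}

}  // namespace

// Solve A x = b once (exposed for operator tests).
// [[Rcpp::export]]
NumericVector cpp_cg_solve(IntegerVector Ap, IntegerVector Ai,
                           NumericVector Ax, NumericVector b,
                           double tol = 1e-8, int maxit = 1000) {
  CSC A{&Ap[0], &Ai[0], &Ax[0], (int)b.size()};
  int n = A.n;
  std::vector<double> dinv(n, 1.0), r(n), z(n), q(n);
  for (int c = 0; c < n; ++c)
    for (int k = Ap[c]; k < Ap[c + 1]; ++k)
      if (Ai[k] == c && Ax[k] != 0.0) dinv[c] = 1.0 / Ax[k];
  NumericVector x(clone(b));
  int it = pcg(A, &b[0], &x[0], dinv.data(), tol, maxit, r, z, q);
  if (it < 0) stop("conjugate gradient did not converge within %d iterations", maxit);
  x.attr("iterations") = it;
  return x;
}

// Full tissue simulation on the node grid.
//  labels: tissue class per node (1 MYO, 2 FIB_FL, 3 FIB_IL)
//  Ap/Ai/Ax: CSC slots of A = diag(md) + K (implicit diffusion system)
//  md: nodal capacitance / dt (the diagonal mass scaling of the rhs)
//  init_states: FS_NSTATE x n_classes settled unit states (column = class)
//  numf_by_class: fibroblast count per tissue class
//  stim_elem/stim_ptr: concatenated 0-based node lists per stimulus with
//    pointers (length n_stim+1); stim_onset/dur/amp per stimulus (s, s, pA)
// [[Rcpp::export]]
List cpp_simulate(IntegerVector labels, IntegerVector Ap, IntegerVector Ai,
                  NumericVector Ax, NumericVector md, NumericMatrix init_states,
                  NumericVector numf_by_class, double ggap, double cm_myo,
                  double cm_fb, IntegerVector stim_elem, IntegerVector stim_ptr,
                  NumericVector stim_onset, NumericVector stim_dur,
                  NumericVector stim_amp, double dt, int n_steps,
                  int sample_every, double cg_tol, int cg_maxit,
                  bool reaction_on = true, bool check_extinction = true,
                  double ext_thresh = -60.0, double ext_ms = 20.0,
                  bool return_states = false) {
  const int N = labels.size();
  if (init_states.nrow() != FS_NSTATE)
    stop("init_states must have %d rows", FS_NSTATE);
  CSC A{&Ap[0], &Ai[0], &Ax[0], N};

  // per-node state storage; init_states is either one column per tissue
  // class or a full FS_NSTATE x N matrix of per-node states
  const bool full_init = init_states.ncol() == N && N > 3;
  std::vector<double> Y((size_t)N * FS_NSTATE);
  for (int e = 0; e < N; ++e) {
    int col = full_init ? e : labels[e] - 1;
    if (col < 0 || col >= init_states.ncol()) stop("bad label at node %d", e + 1);
    for (int k = 0; k < FS_NSTATE; ++k)
      Y[(size_t)e * FS_NSTATE + k] = init_states(k, col);
  }
  std::vector<CellParams> par(numf_by_class.size());
  for (int c = 0; c < (int)par.size(); ++c)
    par[c] = CellParams{numf_by_class[c], ggap, cm_myo, cm_fb};

  const int n_stim = stim_onset.size();
  double last_stim_end = 0.0;
  for (int s = 0; s < n_stim; ++s)
    last_stim_end = std::max(last_stim_end, stim_onset[s] + stim_dur[s]);

  std::vector<double> istim(N, 0.0), V(N), dinv(N, 1.0), r(N), z(N), q(N),
      pcgdir(N);
  for (int c = 0; c < N; ++c)
    for (int k = Ap[c]; k < Ap[c + 1]; ++k)
      if (Ai[k] == c && Ax[k] != 0.0) dinv[c] = 1.0 / Ax[k];
  SymA As = build_sym(A);

  const int n_frames = n_steps / sample_every + 1;
  NumericMatrix movie(N, n_frames);
  NumericVector times(n_frames);
  for (int e = 0; e < N; ++e) movie(e, 0) = Y[(size_t)e * FS_NSTATE + IDX_V];
  times[0] = 0.0;
  int frame = 1;

  const double ext_frames_needed = ext_ms / (sample_every * dt * 1000.0);
  int ext_count = 0;
  std::string termination = "max_time";
  int steps_done = 0;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    // stimulus currents for this step
    bool any_stim = false;
    for (int s = 0; s < n_stim; ++s) {
      if (t >= stim_onset[s] && t < stim_onset[s] + stim_dur[s]) { any_stim = true; break; }
    }
    if (any_stim) {
      std::fill(istim.begin(), istim.end(), 0.0);
      for (int s = 0; s < n_stim; ++s) {
        if (t >= stim_onset[s] && t < stim_onset[s] + stim_dur[s]) {
          for (int k = stim_ptr[s]; k < stim_ptr[s + 1]; ++k)
            istim[stim_elem[k]] += stim_amp[s];
        }
      }
    }
    // reaction
    if (reaction_on) {
      for (int e = 0; e < N; ++e) {
        double is = any_stim ? istim[e] : 0.0;
        int bad = fs_cell_euler(&Y[(size_t)e * FS_NSTATE], is, par[labels[e] - 1], dt);
        if (bad) {
          stop("non-finite state variable %d at element %d, t = %g ms",
               bad, e + 1, t * 1000.0);
        }
      }
    }
    // diffusion: (M/dt + K) V+ = (M/dt) V
    for (int e = 0; e < N; ++e) V[e] = md[e] * Y[(size_t)e * FS_NSTATE + IDX_V];
    std::vector<double> x(N);
    for (int e = 0; e < N; ++e) x[e] = Y[(size_t)e * FS_NSTATE + IDX_V];
    int it = pcg_sym(As, V.data(), x.data(), dinv.data(), cg_tol, cg_maxit,
                     r, z, q, pcgdir);
    if (it < 0)
      stop("conjugate gradient stalled at t = %g ms", t * 1000.0);
    for (int e = 0; e < N; ++e) Y[(size_t)e * FS_NSTATE + IDX_V] = x[e];
    ++steps_done;

    if ((step + 1) % sample_every == 0 && frame < n_frames) {
      double vmax = -1e9;
      for (int e = 0; e < N; ++e) {
        double v = Y[(size_t)e * FS_NSTATE + IDX_V];
        movie(e, frame) = v;
        if (v > vmax) vmax = v;
      }
      times[frame] = (step + 1) * dt;
      ++frame;
      if (check_extinction && (step + 1) * dt > last_stim_end) {
        if (vmax < ext_thresh) {
          if (++ext_count >= ext_frames_needed) { termination = "extinction"; break; }
        } else {
          ext_count = 0;
        }
      }
    }
  }

  List out = List::create(
      _["movie"] = movie(_, Range(0, frame - 1)),
      _["times"] = times[Range(0, frame - 1)],
      _["steps_done"] = steps_done,
      _["termination"] = termination,
      _["duration_s"] = steps_done * dt);
  if (return_states) {
    NumericMatrix fin(FS_NSTATE, N);
    for (int e = 0; e < N; ++e)
      for (int k = 0; k < FS_NSTATE; ++k) fin(k, e) = Y[(size_t)e * FS_NSTATE + k];
    out["states"] = fin;
  }
  return out;
}
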