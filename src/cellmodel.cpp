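// Nygren et al. human atrial myocyte model coupled to the MacCannell-type
// "active" fibroblast used in the Maleckar myocyte-fibroblast model
// (configuration "Active 1").  Parameter values are the published ones;
// the numf identical fibroblasts of one unit share a single state because
// they see identical inputs, so the summed gap current is
// numf * Ggap * (Vmyo - VFb).
//
// All voltage-dependent rate expressions are tabulated on a 0.02 mV grid
// with linear interpolation (relative error ~1e-7), which dominates the
// cost of tissue-scale runs; the same tables serve the single-cell API so
// there is exactly one reaction implementation.
#include "cellmodel.h"
#include <cmath>
#include <vector>

namespace {

const double Rgas = 8314.0;     // mJ/(mol K)
const double Temp = 306.15;     // K
const double Farad = 96487.0;   // C/mol
const double RTF = Rgas * Temp / Farad;  // 26.38 mV

// compartment volumes (nL) and cleft diffusion time constants (s)
const double Vol_i = 0.005884;
const double Vol_c = 0.136 * Vol_i;
const double Vol_d = 0.02 * Vol_i;
const double Vol_rel = 0.0000441;
const double Vol_up = 0.0003969;
const double tau_Na = 14.3, tau_K = 10.0, tau_Ca = 24.7;
const double Na_b = 130.0, K_b = 5.4, Ca_b = 1.8;
const double phi_Na_en = -1.68;  // electroneutral Na influx (pA)

// maximal conductances (nS) / currents (pA)
const double P_Na = 0.0016;       // nL/s
const double g_CaL = 6.75, E_Ca_app = 60.0, k_Ca = 0.025;
const double g_t = 7.5, g_sus = 2.75, g_Ks = 1.0, g_Kr = 0.5, g_K1 = 3.0;
const double g_B_Na = 0.060599, g_B_Ca = 0.078681;
const double I_NaK_max = 70.8253, k_NaK_K = 1.0, k_NaK_Na = 11.0;
const double I_CaP_max = 4.0, k_CaP = 0.0002;
const double k_NaCa = 0.0374842, gam = 0.45, d_NaCa = 0.0003;

// sarcoplasmic reticulum
const double I_up_max = 2800.0, k_cyca = 0.0003, k_srca = 0.5, k_xcs = 0.4;
const double tau_tr = 0.01, tau_di = 0.01;
const double alpha_rel = 200000.0, k_rel_i = 0.0003, k_rel_d = 0.003;
const double r_recov = 0.815;
const double Mg_i = 2.5;

// fibroblast (per-pF densities scaled by Cm_fb = 6.3 pF)
const double fb_g_Kv = 0.25 * 6.3;     // nS
const double fb_g_K1 = 0.4822 * 6.3;   // nS
// background Na conductance calibrated so the uncoupled active fibroblast
// rests at the published -49.6 mV
const double fb_g_BNa = 0.0890;        // nS
const double fb_I_NaK = 2.002 * 6.3;   // pA
const double fb_KmK = 1.0, fb_KmNa = 11.0, fb_B = -200.0, fb_Vrev = -150.0;
const double fb_Nai = 8.5547, fb_Ki = 129.4349, fb_Ko = 5.4, fb_Nao = 130.0;

inline double sq(double x) { return x * x; }

// ---- voltage-rate tables ---------------------------------------------------

const double TAB_VMIN = -150.0, TAB_VMAX = 200.0, TAB_STEP = 0.02;
const int TAB_N = (int)((TAB_VMAX - TAB_VMIN) / TAB_STEP) + 2;
// per-row functions of the membrane voltage
enum {
  F_MBAR, F_TAUM, F_HBAR, F_TAUH1, F_TAUH2,
  F_DLBAR, F_TAUDL, F_FLBAR, F_TAUFL1, F_TAUFL2,
  F_RBAR, F_TAUR, F_SBAR, F_TAUS,
  F_RSUSBAR, F_TAURSUS, F_SSUSBAR, F_TAUSSUS,
  F_NBAR, F_TAUN, F_PABAR, F_TAUPA, F_PI,
  F_EXPG, F_EXPG1, F_GHKV, F_EXPV, F_NAKV,
  F_RFBBAR, F_TAURFB, F_SFBBAR, F_TAUSFB, F_K1F, F_NAKFV,
  F_NFUNC
};

struct Tables {
  std::vector<double> rows;   // TAB_N x F_NFUNC, row-major
  std::vector<double> k1;     // IK1 rectification over x = V - EK
  Tables() : rows((size_t)TAB_N * F_NFUNC), k1(TAB_N) {
    const double EKf = RTF * std::log(fb_Ko / fb_Ki);
    for (int i = 0; i < TAB_N; ++i) {
      double V = TAB_VMIN + i * TAB_STEP;
      double *r = &rows[(size_t)i * F_NFUNC];
      r[F_MBAR] = 1.0 / (1.0 + std::exp((V + 27.12) / -8.21));
      r[F_TAUM] = 1.0 / (4.2e-5 * std::exp(-sq((V + 25.57) / 28.8)) + 2.4e-5);
      r[F_HBAR] = 1.0 / (1.0 + std::exp((V + 63.6) / 5.3));
      r[F_TAUH1] = 1.0 / (0.03 / (1.0 + std::exp((V + 35.1) / 3.2)) + 0.0003);
      r[F_TAUH2] = 1.0 / (0.12 / (1.0 + std::exp((V + 35.1) / 3.2)) + 0.003);
      r[F_DLBAR] = 1.0 / (1.0 + std::exp((V + 9.0) / -5.8));
      r[F_TAUDL] = 1.0 / (0.0027 * std::exp(-sq((V + 35.0) / 30.0)) + 0.002);
      r[F_FLBAR] = 1.0 / (1.0 + std::exp((V + 27.4) / 7.1));
      r[F_TAUFL1] = 1.0 / (0.161 * std::exp(-sq((V + 40.0) / 14.4)) + 0.01);
      r[F_TAUFL2] = 1.0 / (1.3323 * std::exp(-sq((V + 40.0) / 14.2)) + 0.0626);
      r[F_RBAR] = 1.0 / (1.0 + std::exp((V - 1.0) / -11.0));
      r[F_TAUR] = 1.0 / (0.0035 * std::exp(-sq(V / 30.0)) + 0.0015);
      r[F_SBAR] = 1.0 / (1.0 + std::exp((V + 40.5) / 11.5));
      r[F_TAUS] = 1.0 / (0.4812 * std::exp(-sq((V + 52.45) / 14.97)) + 0.01414);
      r[F_RSUSBAR] = 1.0 / (1.0 + std::exp((V + 4.3) / -8.0));
      r[F_TAURSUS] = 1.0 / (0.009 / (1.0 + std::exp((V + 5.0) / 12.0)) + 0.0005);
      r[F_SSUSBAR] = 0.4 / (1.0 + std::exp((V + 20.0) / 10.0)) + 0.6;
      r[F_TAUSSUS] = 1.0 / (0.047 / (1.0 + std::exp((V + 60.0) / 10.0)) + 0.3);
      r[F_NBAR] = 1.0 / (1.0 + std::exp((V - 19.9) / -12.7));
      r[F_TAUN] = 1.0 / (0.7 + 0.4 * std::exp(-sq((V - 20.0) / 20.0)));
      r[F_PABAR] = 1.0 / (1.0 + std::exp((V + 15.0) / -6.0));
      r[F_TAUPA] = 1.0 /
          (0.03118 + 0.21718 * std::exp(-sq((V + 20.1376) / 22.1996)));
      r[F_PI] = 1.0 / (1.0 + std::exp((V + 55.0) / 24.0));
      r[F_EXPG] = std::exp(gam * V / RTF);
      r[F_EXPG1] = std::exp((gam - 1.0) * V / RTF);
      r[F_EXPV] = std::exp(V / RTF);
      r[F_GHKV] = (std::fabs(V) < 1e-9)
                      ? Farad
                      : V * (Farad / RTF) / (r[F_EXPV] - 1.0);
      r[F_NAKV] = (V + 150.0) / (V + 200.0);
      r[F_RFBBAR] = 1.0 / (1.0 + std::exp(-(V + 20.0) / 11.0));
      r[F_TAURFB] = 1.0 /
          ((20.3 + 138.0 * std::exp(-sq((V + 20.0) / 25.9))) * 1e-3);
      r[F_SFBBAR] = 1.0 / (1.0 + std::exp((V + 23.0) / 7.0));
      r[F_TAUSFB] = 1.0 /
          ((1574.0 + 5268.0 * std::exp(-sq((V + 23.0) / 22.7))) * 1e-3);
      r[F_K1F] = (V - EKf) / (1.0 + std::exp(0.0896 * (V - EKf)));
      r[F_NAKFV] = (V - fb_Vrev) / (V - fb_B);
      // IK1 rectification, indexed by x = V - EK on the same grid
      double x = V;
      k1[i] = x / (1.0 + std::exp(1.5 * (x + 3.6) / RTF));
    }
  }
};

inline const Tables &tables() {
  static Tables t;
  return t;
}

struct Row {
  double v[F_NFUNC];
};

inline void lookup_row(double V, Row &out) {
  const Tables &t = tables();
  double u = (V - TAB_VMIN) / TAB_STEP;
  if (u < 0.0) u = 0.0;
  if (u > TAB_N - 2) u = TAB_N - 2;
  int i = (int)u;
  double w = u - i;
  const double *a = &t.rows[(size_t)i * F_NFUNC];
  const double *b = a + F_NFUNC;
  for (int k = 0; k < F_NFUNC; ++k) out.v[k] = a[k] + w * (b[k] - a[k]);
}

inline double lookup_k1(double x) {
  const Tables &t = tables();
  double u = (x - TAB_VMIN) / TAB_STEP;
  if (u < 0.0) u = 0.0;
  if (u > TAB_N - 2) u = TAB_N - 2;
  int i = (int)u;
  double w = u - i;
  return t.k1[i] + w * (t.k1[i + 1] - t.k1[i]);
}

}  // namespace

void fs_cell_initial(double *y) {
  y[IDX_V] = -74.2525;
  y[IDX_NA_C] = 130.011; y[IDX_K_C] = 5.3581; y[IDX_CA_C] = 1.8147;
  y[IDX_NA_I] = 8.5547;  y[IDX_K_I] = 129.435;
  y[IDX_CA_I] = 6.729e-5; y[IDX_CA_D] = 7.2495e-5;
  y[IDX_M] = 0.0032017; y[IDX_H1] = 0.8814; y[IDX_H2] = 0.8742;
  y[IDX_DL] = 1.3005e-5; y[IDX_FL1] = 0.9986; y[IDX_FL2] = 0.9986;
  y[IDX_R] = 0.0010678; y[IDX_S] = 0.949;
  y[IDX_RSUS] = 1.5949e-4; y[IDX_SSUS] = 0.9912;
  y[IDX_N] = 0.0048357; y[IDX_PA] = 0.0001;
  y[IDX_F1] = 0.4284; y[IDX_F2] = 0.0028;
  y[IDX_CA_UP] = 0.6646; y[IDX_CA_REL] = 0.6465;
  y[IDX_OC] = 0.0275; y[IDX_OTC] = 0.0133;
  y[IDX_OTMGC] = 0.1961; y[IDX_OTMGMG] = 0.7094; y[IDX_OCALSE] = 0.4369;
  y[IDX_VFB] = -49.6; y[IDX_RFB] = 0.0; y[IDX_SFB] = 1.0;
}

void fs_cell_derivs(const double *y, double *dy, double i_stim,
                    const CellParams &p) {
  const double V = y[IDX_V];
  const double Na_c = y[IDX_NA_C], K_c = y[IDX_K_C], Ca_c = y[IDX_CA_C];
  const double Na_i = y[IDX_NA_I], K_i = y[IDX_K_I];
  const double Ca_i = y[IDX_CA_I], Ca_d = y[IDX_CA_D];

  Row rw;
  lookup_row(V, rw);

  const double E_Na = RTF * std::log(Na_c / Na_i);
  const double E_K = RTF * std::log(K_c / K_i);
  const double E_Ca = 0.5 * RTF * std::log(Ca_c / Ca_i);

  // INa (GHK-type): exp((V - ENa)/RTF) = exp(V/RTF) * Na_i / Na_c
  const double ghk = P_Na * Na_c * rw.v[F_GHKV] *
                     (rw.v[F_EXPV] * Na_i / Na_c - 1.0);
  const double INa = ghk * y[IDX_M] * y[IDX_M] * y[IDX_M] *
                     (0.9 * y[IDX_H1] + 0.1 * y[IDX_H2]);

  const double f_Ca = Ca_d / (Ca_d + k_Ca);
  const double ICaL = g_CaL * y[IDX_DL] *
      (f_Ca * y[IDX_FL1] + (1.0 - f_Ca) * y[IDX_FL2]) * (V - E_Ca_app);

  const double It = g_t * y[IDX_R] * y[IDX_S] * (V - E_K);
  const double Isus = g_sus * y[IDX_RSUS] * y[IDX_SSUS] * (V - E_K);
  const double IKs = g_Ks * y[IDX_N] * (V - E_K);
  const double IKr = g_Kr * y[IDX_PA] * rw.v[F_PI] * (V - E_K);
  const double IK1 = g_K1 * std::pow(K_c, 0.4457) * lookup_k1(V - E_K);
  const double IBNa = g_B_Na * (V - E_Na);
  const double IBCa = g_B_Ca * (V - E_Ca);
  const double nai15 = Na_i * std::sqrt(Na_i);
  const double INaK = I_NaK_max * (K_c / (K_c + k_NaK_K)) *
      (nai15 / (nai15 + 36.4829)) *  // 11^1.5
      rw.v[F_NAKV];
  const double ICaP = I_CaP_max * Ca_i / (Ca_i + k_CaP);
  const double nac3 = Na_c * Na_c * Na_c, nai3 = Na_i * Na_i * Na_i;
  const double INaCa = k_NaCa *
      (nai3 * Ca_c * rw.v[F_EXPG] - nac3 * Ca_i * rw.v[F_EXPG1]) /
      (1.0 + d_NaCa * (Ca_i * nac3 + Ca_c * nai3));

  // gap-junction loading by numf identical fibroblasts
  const double Vfb = y[IDX_VFB];
  const double I_gap_per_fb = p.ggap * (V - Vfb);

  const double I_myo = INa + ICaL + It + Isus + IK1 + IKr + IKs +
                       IBNa + IBCa + INaK + ICaP + INaCa;
  dy[IDX_V] = -(I_myo + i_stim + p.numf * I_gap_per_fb) / p.cm_myo;

  // gating kinetics (tabulated steady states and inverse time constants)
  dy[IDX_M] = (rw.v[F_MBAR] - y[IDX_M]) * rw.v[F_TAUM];
  dy[IDX_H1] = (rw.v[F_HBAR] - y[IDX_H1]) * rw.v[F_TAUH1];
  dy[IDX_H2] = (rw.v[F_HBAR] - y[IDX_H2]) * rw.v[F_TAUH2];
  dy[IDX_DL] = (rw.v[F_DLBAR] - y[IDX_DL]) * rw.v[F_TAUDL];
  dy[IDX_FL1] = (rw.v[F_FLBAR] - y[IDX_FL1]) * rw.v[F_TAUFL1];
  dy[IDX_FL2] = (rw.v[F_FLBAR] - y[IDX_FL2]) * rw.v[F_TAUFL2];
  dy[IDX_R] = (rw.v[F_RBAR] - y[IDX_R]) * rw.v[F_TAUR];
  dy[IDX_S] = (rw.v[F_SBAR] - y[IDX_S]) * rw.v[F_TAUS];
  dy[IDX_RSUS] = (rw.v[F_RSUSBAR] - y[IDX_RSUS]) * rw.v[F_TAURSUS];
  dy[IDX_SSUS] = (rw.v[F_SSUSBAR] - y[IDX_SSUS]) * rw.v[F_TAUSSUS];
  dy[IDX_N] = (rw.v[F_NBAR] - y[IDX_N]) * rw.v[F_TAUN];
  dy[IDX_PA] = (rw.v[F_PABAR] - y[IDX_PA]) * rw.v[F_TAUPA];

  // SR Ca handling
  const double I_up = I_up_max *
      (Ca_i / k_cyca - k_xcs * k_xcs * y[IDX_CA_UP] / k_srca) /
      ((Ca_i + k_cyca) / k_cyca + k_xcs * (y[IDX_CA_UP] + k_srca) / k_srca);
  const double I_tr = (y[IDX_CA_UP] - y[IDX_CA_REL]) * 2.0 * Farad * Vol_rel /
                      tau_tr;
  const double relf = y[IDX_F2] / (y[IDX_F2] + 0.25);
  const double I_rel = alpha_rel * relf * relf * (y[IDX_CA_REL] - Ca_i);
  const double act_i = sq(sq(Ca_i / (Ca_i + k_rel_i)));
  const double act_d = sq(sq(Ca_d / (Ca_d + k_rel_d)));
  const double r_act = 203.8 * (act_i + act_d);
  const double r_inact = 33.96 + 339.6 * act_i;
  dy[IDX_F1] = r_recov * (1.0 - y[IDX_F1] - y[IDX_F2]) - r_act * y[IDX_F1];
  dy[IDX_F2] = r_act * y[IDX_F1] - r_inact * y[IDX_F2];

  const double dOCalse = 480.0 * y[IDX_CA_REL] * (1.0 - y[IDX_OCALSE]) -
                         400.0 * y[IDX_OCALSE];
  dy[IDX_OCALSE] = dOCalse;
  const double dOC = 200000.0 * Ca_i * (1.0 - y[IDX_OC]) - 476.0 * y[IDX_OC];
  const double dOTC = 78400.0 * Ca_i * (1.0 - y[IDX_OTC]) - 392.0 * y[IDX_OTC];
  const double dOTMgC = 200000.0 * Ca_i *
      (1.0 - y[IDX_OTMGC] - y[IDX_OTMGMG]) - 6.6 * y[IDX_OTMGC];
  const double dOTMgMg = 2000.0 * Mg_i *
      (1.0 - y[IDX_OTMGC] - y[IDX_OTMGMG]) - 666.0 * y[IDX_OTMGMG];
  dy[IDX_OC] = dOC; dy[IDX_OTC] = dOTC;
  dy[IDX_OTMGC] = dOTMgC; dy[IDX_OTMGMG] = dOTMgMg;

  dy[IDX_CA_UP] = (I_up - I_tr) / (2.0 * Vol_up * Farad);
  dy[IDX_CA_REL] = (I_tr - I_rel) / (2.0 * Vol_rel * Farad) - 31.0 * dOCalse;
  const double I_di = (Ca_d - Ca_i) * 2.0 * Farad * Vol_d / tau_di;
  dy[IDX_CA_D] = -(ICaL + I_di) / (2.0 * Vol_d * Farad);
  dy[IDX_CA_I] = -(-I_di + IBCa + ICaP - 2.0 * INaCa + I_up - I_rel) /
                     (2.0 * Vol_i * Farad) -
                 (0.045 * dOC + 0.08 * dOTC + 0.16 * dOTMgC);

  const double na_flux = INa + IBNa + 3.0 * INaK + 3.0 * INaCa + phi_Na_en;
  const double k_flux = It + Isus + IK1 + IKs + IKr - 2.0 * INaK;
  dy[IDX_NA_C] = (Na_b - Na_c) / tau_Na + na_flux / (Vol_c * Farad);
  dy[IDX_K_C] = (K_b - K_c) / tau_K + k_flux / (Vol_c * Farad);
  dy[IDX_CA_C] = (Ca_b - Ca_c) / tau_Ca +
      (ICaL + IBCa + ICaP - 2.0 * INaCa) / (2.0 * Vol_c * Farad);
  dy[IDX_NA_I] = -na_flux / (Vol_i * Farad);
  dy[IDX_K_I] = -k_flux / (Vol_i * Farad);

  // --- fibroblast (shared by the numf coupled fibroblasts) ---
  Row rf;
  lookup_row(Vfb, rf);
  const double E_Na_fb = RTF * std::log(fb_Nao / fb_Nai);
  const double E_K_fb = RTF * std::log(fb_Ko / fb_Ki);
  const double IKv = fb_g_Kv * y[IDX_RFB] * y[IDX_SFB] * (Vfb - E_K_fb);
  const double IK1f = fb_g_K1 * rf.v[F_K1F];
  const double nai15f = fb_Nai * std::sqrt(fb_Nai);
  const double INaKf = fb_I_NaK * (fb_Ko / (fb_Ko + fb_KmK)) *
      (nai15f / (nai15f + 36.4829)) * rf.v[F_NAKFV];
  const double IbNaf = fb_g_BNa * (Vfb - E_Na_fb);
  dy[IDX_VFB] = -(IKv + IK1f + INaKf + IbNaf - I_gap_per_fb) / p.cm_fb;

  dy[IDX_RFB] = (rf.v[F_RFBBAR] - y[IDX_RFB]) * rf.v[F_TAURFB];
  dy[IDX_SFB] = (rf.v[F_SFBBAR] - y[IDX_SFB]) * rf.v[F_TAUSFB];
}

int fs_cell_euler(double *y, double i_stim, const CellParams &p, double dt) {
  double dy[FS_NSTATE];
  fs_cell_derivs(y, dy, i_stim, p);
  for (int k = 0; k < FS_NSTATE; ++k) {
    y[k] += dt * dy[k];
    if (!std::isfinite(y[k])) return k + 1;
  }
  // forward Euler can overshoot a concentration to <= 0 during extreme
  // depolarizations; floor them to keep the rate expressions defined
  static const int conc_idx[] = {IDX_NA_C, IDX_K_C, IDX_CA_C, IDX_NA_I,
                                 IDX_K_I, IDX_CA_I, IDX_CA_D, IDX_CA_UP,
                                 IDX_CA_REL};
  for (int k : conc_idx) {
    if (y[k] < 1e-9) y[k] = 1e-9;
  }
  return 0;
}
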