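#ifndef FIBROSLAB_CELLMODEL_H
#define FIBROSLAB_CELLMODEL_H

// Coupled-unit state layout: Nygren human atrial myocyte (29 states)
// followed by one shared active fibroblast (3 states).  All units follow
// the model's native system: time s, voltage mV, current pA, capacitance
// nF, volume nL, concentration mM.
#define FS_NSTATE 32

enum {
  IDX_V = 0,
  IDX_NA_C, IDX_K_C, IDX_CA_C,
  IDX_NA_I, IDX_K_I, IDX_CA_I, IDX_CA_D,
  IDX_M, IDX_H1, IDX_H2,
  IDX_DL, IDX_FL1, IDX_FL2,
  IDX_R, IDX_S,
  IDX_RSUS, IDX_SSUS,
  IDX_N, IDX_PA,
  IDX_F1, IDX_F2,
  IDX_CA_UP, IDX_CA_REL,
  IDX_OC, IDX_OTC, IDX_OTMGC, IDX_OTMGMG, IDX_OCALSE,
  IDX_VFB, IDX_RFB, IDX_SFB
};

struct CellParams {
  double numf;     // fibroblasts coupled to the myocyte
  double ggap;     // gap junctional conductance per fibroblast (nS)
  double cm_myo;   // myocyte membrane capacitance (nF)
  double cm_fb;    // fibroblast membrane capacitance (nF)
};

void fs_cell_initial(double *y);
// Derivatives of the coupled unit; i_stim in pA (depolarizing < 0).
void fs_cell_derivs(const double *y, double *dy, double i_stim,
                    const CellParams &p);
// One forward-Euler step in place; returns 0 on success, 1 on non-finite.
int fs_cell_euler(double *y, double i_stim, const CellParams &p, double dt);

#endif
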