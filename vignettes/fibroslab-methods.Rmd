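---
title: "fibroslab: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fibroslab: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

`fibroslab` simulates a 40 x 40 x 3.6 mm slab of atrial tissue whose wall
carries two structurally distinct kinds of fibrotic remodeling:

* **Intramural fibrosis** — patchy conduction blocks inside the wall.  Two
  thick fibrotic layers (0.8 mm each) and one thin fibrotic layer (0.4 mm)
  carry fibrotic patches built from overlapping cylindrical blobs of
  2.6 mm radius.  The thin layer is not drawn independently: it is fibrotic
  exactly where the patches of the two thick layers overlap in plane.  The
  intramural fibrosis degree (IFD) is the fibrotic element fraction of
  these three layers, in percent.
* **Endo-epicardial dissociation** — two isolation layers (0.4 mm each)
  of zero-conductivity fibrotic tissue separate the endocardial and
  epicardial sheets from the wall.  Myocardial blobs of 2.5 mm radius
  punched into these layers are the only transmural conduction routes.
  The endo-epicardial dissociation degree (EDD) is the fibrotic element
  fraction of the isolation layers.

The stack, from endocardium to epicardium, is
ENDO | ISOLATION | THICK | THIN | THICK | ISOLATION | EPI — nine element
slices of 0.4 mm, 90,000 cubic elements at full scale.  To keep every
myocardial patch a viable route, fibrotic blobs in a thick layer are
resampled until their rasterization avoids the in-plane projection of
every myocardial patch of the adjacent isolation layer.

## Stochastic microstructure generation

Blob centers are drawn uniformly over the footprint, with three balance
rules that operationalize "avoid gathering in the middle or scattering on
the edge": centers at least half a radius from the footprint edge, the
centroid of each blob set within 4 mm of the slab center (scaled
proportionally for other footprints), and the RMS distance of centers from
the slab center within +/-20% of its expectation under the uniform law.
Whole sets are resampled until the criterion holds (budget 10,000
proposals).

IFD is *controlled*, EDD only *recorded*: whole geometries are rejected
until the realized IFD falls inside the tabulated window for the
configured fibrotic blob count (budget 500 geometries).  Windows for
untabulated stochastic counts (27, 28, ...) are linearly interpolated
between the tabulated rows.  The four study groups differ only in how
blob counts and layouts are drawn:

* stochastic: myocardial count uniform on 5-19, fibrotic count given;
* interrelated: thirteen printed (myocardial, fibrotic) count pairs built
  from one base geometry by adding myocardial blobs and adding/removing
  fibrotic blobs, removal always taking the highest-indexed blobs so the
  lowest-indexed blobs form a common core shared by the whole series;
* fibrosis-degree-controlled: both families redrawn per replicate at
  fixed counts;
* dissociation-degree-controlled: one fixed myocardial layout shared by
  all replicates, fibrotic layouts redrawn.

When a member of the interrelated series misses its IFD window after an
edit, only the blobs added in that step are resampled; if half the retry
budget passes, the non-core fibrotic blobs (indices above the
never-removed core) are redrawn as well.  The common core is preserved
either way.

# Electrophysiology

Each node of the computational grid carries one human atrial myocyte
(Nygren model, full published 29-variable state) electrotonically loaded
by `numf` identical active fibroblasts (MacCannell-type, as used in the
Maleckar coupling study, "Active 1"): membrane potential and two
delayed-rectifier gates, fixed intracellular ion concentrations.  Because
the `numf` fibroblasts of a unit are identical and see identical inputs,
one shared fibroblast state represents all of them and the summed gap
current is `numf * Ggap * (Vmyo - VFb)`.  Myocardial tissue carries
`numf = 3`; fibrotic tissue (both kinds) carries `numf = 45`, which
depolarizes its resting potential to about -51 mV and largely inactivates
its sodium current — fibrotic tissue is excitable only weakly, and slowly
conducting through its reduced conductivity (0.1 mS/cm; 0 in isolation
layers).

Parameters the reference material does not print, chosen once and fixed:

* `Cm_fb = 6.3 pF` and `Ggap = 0.5 nS` per fibroblast, from the published
  active-fibroblast coupling configuration.
* The fibroblast background sodium conductance was set to 0.089 nS so the
  uncoupled active fibroblast rests at its published -49.6 mV (the other
  recalled current densities left the equilibrium near -78 mV, which
  inverts the physiological direction of every coupling effect).  No
  package behavior of scientific interest depends on the exact value, only
  on the ~-50 mV rest.
* `beta = 350 /cm` with a 1 uF/cm^2 specific capacitance.  The
  conduction-velocity constraint (a plane wave in myocardial tissue within
  the physiological atrial range) admits roughly 120-650 /cm; within that
  band the value is fixed by a second qualitative requirement of the
  model: transmural conduction through 2.5 mm isolation-layer patches must
  be safe, which needs the smaller space constant of the upper part of the
  band.  At 350 /cm the plane-wave velocity is 0.38 m/s and patch
  conduction succeeds; at 200 /cm (0.53 m/s) the patch-to-wall expansion
  blocks everywhere, which would contradict the breakthrough phenomenology
  the model exists to study.

A long-standing property of the Nygren model is a slow drift of the
potassium-driven resting state; after 30 s of settling the residual drift
is below 0.02 mV/s for the myocardial unit.  The heavily loaded `numf =
45` unit wobbles by up to ~1 mV/s around its depolarized rest — this is
reported by a warning and is irrelevant to wave dynamics.  Settled states
are cached per parameter set.

## Numerics

All cell states advance by forward Euler at a fixed 10 us step.  Because
the L-type driving force is the published linear approximation
`g_CaL (V - 60 mV)`, an overdriven upstroke into partially refractory
tissue can transiently push the dyadic calcium concentration negative
under explicit stepping; concentrations are floored at 1e-9 mM.  This
guard never engages in ordinary paced activity.

The diffusion term uses trilinear hexahedral finite elements with lumped
mass on the element-corner node grid `(nx+1) x (ny+1) x (nz+1)`; each
element adds its local brick stiffness scaled by its conductivity, so
zero-conductivity elements add nothing: a fully fibrotic isolation layer
is an exact internal zero-flux barrier, while a myocardial patch couples
the two sides.  Each 10 us step is operator-split: reaction (explicit)
then implicit diffusion, `(M/dt + K) V+ = (M/dt) V`, solved by
Jacobi-preconditioned conjugate gradients to a relative residual of
1e-8.

The element-centered alternative (voltages at element centers, 7-point
face-flux stencil) was implemented first and rejected: a voltage unknown
inside a one-element-thick transmural channel then sits in a voltage
divider between the endocardial plateau above and the resting wall below,
saturating near the midpoint (~-42 mV) regardless of the surface-to-volume
scaling, so no transmural conduction is possible through 0.4 mm
isolation-layer patches.  With nodal unknowns the patch interface nodes
belong to the endocardial sheet itself and the divider disappears.  This
resolves the open choice between element-centered and nodal unknowns in
favor of nodal.

## Stimulation

A line stimulus S1 along the left edge of the endocardial surface at
t = 1 ms is followed by an area stimulus S2 over the lower-left quadrant,
both 2 ms long at twice the diastolic threshold of the coupled tissue
(calibrated once: threshold ~-5.5 nA per node, default amplitude -11 nA).
The reference protocol places S2 at 280 ms; the vulnerable window in which
S2 actually breaks the S1 recovery tail depends on the action potential
duration and conduction velocity, hence on the coupling parameters left
open above.  For the defaults here the window was measured once (no
wavebreak at 260-285 ms; sustained wavebreak at 225-245 ms, verified on
both 24 and 40 mm footprints), and the packaged default S2 time is
235 ms.  `s1s2_protocol(..., s2_time = 0.280)` reproduces the printed
timing.

## Desk scale

Paper-scale runs (90,000 elements, 10 s) need cluster time.  The desk
preset keeps the element size, the nine-slice architecture, the cell
models and the S1-S2 protocol, and shrinks the footprint to 24 x 24 mm
with a 1 s horizon and a proportionally scaled stability threshold.  The
footprint cannot be shrunk much further: wavebreak needs the S1
activation-time gradient (footprint crossing time, ~44 ms at 24 mm) to
overlap the repolarization dispersion, which is why an 8 mm desk slab
cannot initiate spirals at all.  Blob counts scale with footprint area;
radii are kept (they set the physics of transmural connectivity), so the
tabulated IFD windows — defined for the 40 mm footprint — do not apply at
desk scale and desk geometries are generated with explicit windows.

# Analysis

**Phase and phase singularities.**  The activation phase is the
delayed-coordinate angle `theta(t) = atan2(V(t + tau) - Vmean, V(t) -
Vmean)` with `tau = 30 ms` and the per-node mean over the whole record
(including the initiation transient; an exclusion window is available).
Flat samples (both arguments zero) are undefined and excluded.  A phase
singularity is an elementary 2 x 2 loop whose wrapped phase differences
sum to +/-2 pi; position is the loop center, chirality the winding sign.
Tracking links detections 1 ms apart within a 1 mm gate (a tip moving
below 1 m/s cannot travel farther), nearest first, exact ties to the
older track.  Statistics: mean track lifespan, generation rate (tracks
per second of record), the 1 ms count series, and its first-500 ms and
whole-record means.  A simulation is *stable* when activity outlives 10 s
(strict inequality); the desk preset scales this threshold with its
shortened horizon.

**Electrograms.**  The unipolar electrogram is the unbounded-volume
integral `Phi_e = -K * sum grad(V) . grad(1/R) dv` over tissue, with the
gradient by central differences (one-sided at boundaries and across
zero-conductivity barriers so they do not masquerade as dipoles), K = 1
(only shape and frequency content are analysed downstream), and elements
within half an element of the site excluded (integrable singularity).
Bipolar electrograms subtract two unipolar signals 6 mm apart; the
pseudo-ECG subtracts the two far-field unipolar signals 3 cm outside the
endocardial and epicardial sheet centers.  Power spectra are periodograms
of the mean-removed signals, normalized so the summed spectrum equals the
variance (Parseval).

**Breakthroughs and intramural re-entry.**  An activation component is a
set of 8-connected nodes crossing -40 mV upward in the same 1 ms frame; a
component with no previous-frame wave within one node is parentless.  A
parentless component over the projection of an isolation-layer myocardial
patch opens a breakthrough candidate; it is veritable if its wave grows
to at least 25 nodes (~4 mm^2) or merges with another wave, otherwise it
is recorded as annihilated.  The -40 mV threshold and the 25-node extent
are configurable (the reference definitions are qualitative).
Intramural re-entry is detected in two stages: patches seeding at least
three successive breakthroughs at fixed location with period dispersion
below 10%, on both surfaces with matching periods; then confirmation that
in each anchor period the activity in the connection wall forms one
26-connected component linking the two anchor patches — a repeating
closed transmural circuit.

**Group statistics.**  Episode durations feed a Kaplan-Meier
product-limit estimate (runs alive at the horizon are censored — the
reference leaves this choice open), and ranked-subset comparisons: rows
ranked by EDD or IFD (ties by simulation id), first/last k subsets
(28 of 65, or 20 of the 42 non-stable, at paper scale), compared by
two-sample Kolmogorov-Smirnov and Welch t tests, significance at 0.05.
The KS test is reported alongside the t test rather than used as a
normality screen, since the reference's KS usage is ambiguous.

# What the tests establish, and what they do not

The test suite verifies the geometry constraints exactly (label
partitions, projection-constraint audits, window membership,
determinism), the cell model against an independent R transcription of
the published equations integrated by RK4 (no reference implementation
is installable in the build environment, so transcription and integrator
errors are covered but a shared misreading of the published equations
would not be), the discrete operators against hand-assembled stiffness
and conservation identities, the phase/tracking/electrogram/statistics
tools against closed-form and brute-force oracles, and the qualitative
reproduction at desk scale: S1-S2 wavebreak with endocardial phase
singularities, epicardial breakthroughs only over patch projections, and
zero transmural conduction at EDD = 100%.  Paper-scale quantitative
outcomes (episode-duration survival curves over 65 stochastic runs, PS
lifespan bands, re-entry incidence) are out of desk-scale reach and are
not claimed by any test.
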