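---
title: "Modelling Ca2+ microdomains in ER-PM junctions with socesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Ca2+ microdomains in ER-PM junctions with socesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Resting and weakly adherent T cells show brief, spatially confined
cytosolic Ca2+ elevations ("Ca2+ microdomains": tens of milliseconds,
a few hundred nanomolar, well below optical resolution) in the junctions
where the endoplasmic reticulum (ER) approaches the plasma membrane (PM) to
within ~15 nm.  These junctions host the machinery of store-operated Ca2+
entry (SOCE): ORAI1 channels in the PM, gated by the ER Ca2+ sensor STIM2,
SERCA pumps returning Ca2+ to the ER, and -- just outside the junction --
immobile IP3 receptor (IP3R) clusters whose spontaneous openings locally
deplete the sub-PM ER.  `socesim` is a deterministic reaction-diffusion
model of one such junction.  It asks, quantitatively: how much Ca2+ do
partially open ORAI1 channels deliver at full ER load, and how does local
ER depletion by an open IP3R change that through STIM2-mediated gating?

## Model

### Geometry

The computational domain is a 400 x 400 x 500 nm box of cytosol whose top
face is the PM.  A truncated cone of ER ("sub-PM ER": top radius 100 nm at
15 nm below the PM, bottom radius 200 nm at the box bottom, depth 485 nm)
is embedded in it; the 200 nm-diameter, 15 nm-tall cylinder between the PM
and the flat ER top face is the junction proper.  Channels and pumps are
circular flux patches:

* 5 ORAI1 channels on a 40 nm-radius ring on the PM (47.0 nm spacing),
* 10 SERCA pumps on a 70 nm ring on the ER top face (~43 nm spacing),
* 8 IP3Rs on the cone's lateral face, 90 nm below the PM, where the cone
  taper puts them on a 115.5 nm ring (~88 nm spacing, consistent with the
  ~90 nm inter-receptor distance reported for licensed IP3R clusters).

```{r}
library(socesim)
geom <- junction_geometry()
layout <- channel_layout(geom)
write_layout_manifest(layout, "layout.tsv")
```

### Fields and boundary conditions

Two fields are solved: cytosolic Ca2+ \(C_C\) on the box minus the cone and
luminal Ca2+ \(C_S\) on the cone, each obeying a pure diffusion equation
\(\partial_t C - D \nabla^2 C = 0\) with \(D_C = 220\ \mu m^2/s\) and
\(D_S = 10\ \mu m^2/s\) (alternative 110).  There is no bulk reaction term:
Ca2+ buffering is deliberately omitted (short time scales; buffers near the
pore mouths are saturated), so all chemistry lives on the boundaries:

* Dirichlet \(C_C = 30\) nM on the lateral faces of the box (bulk cytosol)
  and \(C_S = 400\) μM on the cone bottom (bulk ER at rest);
* no-flux on the PM, the ER membrane and the box bottom, except across
  patches;
* ORAI1 patch: molar rate \(f(C_S^{loc})\, I_{ORAI}/(zF)\) into the
  cytosol, with the extracellular side an infinite reservoir;
* IP3R patch: \(\frac{I_{IP3R}}{zF}\,\frac{C_S^m - C_C^m}{C_{S,0}-C_{C,0}}\),
  the unitary current scaled by the actual trans-pore gradient, applied
  with opposite signs on the luminal and cytosolic faces; the mouth
  concentrations \(C^m\) are the area averages over the two pore faces,
  which is well defined under mesh refinement and makes the release flux
  self-limiting as the local ER empties;
* SERCA patch: a bidirectional second-order Hill pump,
  \(V_{max}\,[(C_C^m/K_C)^2 - (C_S^m/K_S)^2] / [1 + (C_C^m/K_C)^2 +
  (C_S^m/K_S)^2]\), with \(K_S/K_C = C_{S,0}/C_{C,0}\) so the net flux is
  exactly zero at rest.

### Discrete ORAI1 gating

STIM2 is not modelled as a molecule.  Instead each ORAI1 channel carries an
open fraction \(f \in [0,1]\) that is a piecewise-constant, non-increasing
function of the ER Ca2+ it senses: the average \(C_S\) over a cube of edge
108 nm centred on the luminal mouth of its associated IP3R (each channel is
paired with its nearest receptor).  The default table is anchored at the
three regimes the biology fixes -- 21% at full ER (STIM2-bound ORAI1 opens
only minimally), 50% once the sensed average falls to ~330 μM, and graded
steps (79%, 100%) at deeper depletion following the published graded
activation of ORAI1:

```{r}
gating_table()
orai_open_fraction(gating_table(), c(400, 330, 100))  # 0.21 0.50 1.00
```

Because \(f\) feeds back on the field that determines the sensed average,
the steady state is a discrete fixed point: solve the fields at the current
assignment, re-average, re-look-up, repeat.  The assignment almost always
stabilises in a couple of iterations; if it ever alternates between two
assignments (possible when a sensed average sits exactly on a breakpoint),
the smaller open fraction is taken per channel, which is deterministic and
conservative.  A cap of 20 iterations raises a solver failure.

## Numerical method

### Why not a body-fitted FEM mesh

The pores are minuscule compared with the domain: the ORAI1 pore disc used
here has a 0.8 nm radius inside a 400 nm box.  Resolving that geometrically
would require ~0.4 nm elements at the patch -- infeasible in 3D.  The
package instead exploits the linearity of the diffusion problem:

1. **Singularity subtraction.**  Each open patch contributes an analytic
   half-space kernel \(u_p = s_p Q_p / (2\pi D r)\) centred on a point of
   the discrete boundary (a patch on a flat grid plane keeps its exact
   centre; on the stair-stepped cone wall the point snaps to the nearest
   boundary face centre, where the spherically symmetric kernel has exactly
   zero normal flux through its own face).  The kernel carries the entire
   pore flux and the entire near-field singularity.
2. **Smooth remainder on a graded rectilinear grid.**  The remainder field
   solves the same operator with (a) Neumann data that cancels the kernels'
   flux through every other boundary face (face-integrated by quadrature,
   refined near the patches) and (b) Dirichlet data that re-pins the open
   boundaries.  The remainder is smooth on the grid scale, so a
   cell-centered finite-volume scheme on a tensor-product grid (fine zone
   covering the junction and all patches, geometric grading outside)
   resolves it cheaply.
3. **One factorisation, many scenarios.**  Kernels and compensation scale
   as \(Q/D\), so the assembled operator is geometry-only.  One sparse
   Cholesky factorisation per sub-domain (cached, LRU-bounded) serves every
   gating state, every Picard iteration and every diffusion coefficient.

Pore-centre values are evaluated as the analytic uniform-flux disc centre
value \(Q/(\pi a D)\) of the patch's own rate plus the environment (other
kernels and the remainder); mouth averages use the disc-surface average
\(8/(3\pi)\) of the centre value.  The IP3R rate, which depends on its own
mouth averages, is updated semi-implicitly (the self-term is solved in
closed form), and the weakly nonlinear SERCA rates by damped Picard
iteration to a relative tolerance of 1e-8 (cap 80 iterations).

The transient mode integrates the full fields (no subtraction) with
implicit Euler and patch fluxes spread over the membrane faces of each
patch footprint; pore-scale peaks are not meaningful in this mode, but
junction-scale averages are, and its steady limit agrees with the
subtraction solver to well under 2% (tested).  Default step 0.5 ms.

### Verification

The `analytic_oracle` layer provides the closed forms the solver is tested
against: the membrane point-source field \(C_{bg} + Q/(2\pi D r)\), the
disc-centre value \(Q/(\pi a D)\), superposition, and a Brownian-walker
Monte Carlo for first-exit (residence) times whose disc closed form is
\(R^2/4D\).  The test suite checks, among others:

* solver vs point-source oracle within 5% at 10-50 nm on a flat-PM
  geometry (a 2 x 2 x 1 μm box with one channel and no ER);
* exact superposition with pumps off;
* global flux conservation (channel influx = Dirichlet outflow) to <1%;
* junction-average stability under sqrt(2) mesh refinement to <2%;
* transient plateau/collapse behaviour and the zero-window identity.

### Problem sizes

The production profile (`mesh_profile("default")`) uses a 6 nm fine zone,
25 nm bulk spacing, ~100k-140k cells and factorises in seconds; the
`coarse` profile (10/30 nm, ~35k cells) is used for the broad property
sweeps in the test suite, whose observables agree with the production
profile to a few percent.  All scenario solves used by the tests and the
acceptance script complete in well under a minute each on one CPU.

## Parameters, defaults and their provenance

| parameter | default | role |
|---|---|---|
| \(I_{ORAI}\) | 2.1 fA | unitary full-open ORAI1 current; chosen so that 5 channels x 21% x 44 ms pass ~300 ions |
| \(I_{IP3R}\) | 0.064 pA | unitary IP3R current at the resting gradient (published estimate) |
| \(D_C, D_S\) | 220, 10 μm²/s | cytosolic / ER diffusion coefficients; \(D_S = 110\) models low ER buffering or tortuosity |
| \(C_{C,0}, C_{S,0}\) | 30 nM, 400 μM | resting concentrations, also the Dirichlet values |
| ORAI pore radius | 0.8 nm | calibrated: one channel at 21% gives ~4 μM at the pore centre via \(Q/(\pi a D)\) |
| IP3R patch radius | 7 nm | calibrated jointly (see below) |
| SERCA patch radius | 5 nm | results insensitive; any small value |
| \(V_{max}\), \(K_C\) | 2e-20 mol/s, 50 μM | bidirectional Hill-2 pump; \(K_S\) fixed by rest equilibrium |
| gating table | 0.21 / 0.5 / 0.79 / 1.0 at 360 / 250 / 150 μM | anchored at the three published regimes, graded steps between |
| sensing cube edge | 108 nm | see "interpretation decisions" |
| event window | 44 ms | observed microdomain lifetime |

All of these are config-overridable (`flux_params()`, `channel_layout()`,
YAML configs); the pore radii, the gating breakpoints and the SERCA
constants are calibrated stand-ins for unpublished supplementary values and
are labelled as such here.

### The IP3R patch-radius calibration

Two published anchors constrain the IP3R pore patch: the cytosolic mouth
reaches ~16 μM, and the ER average sensed in the 108 nm cube drops to
~330 μM (at \(D_S = 10\)).  Under the area-averaged mouth convention the
release flux is self-limiting -- the luminal self-term
\(\propto Q/(a D_S)\) depresses the very gradient that drives \(Q\) -- so
the two anchors pull the radius in opposite directions: a large patch
(e.g. 24 nm) floods its own luminal mouth and caps the cytosolic peak near
10 μM, a tiny patch starves the sensed depletion.
`calibrate_ip3r_radius()` solves the self-consistent closed-form model
(disc self-terms on both faces plus the cone's quasi-1D access resistance
to the ER bulk) over candidate radii and minimises the joint relative error
to both anchors, subject to the sensed average staying clearly below the
360 μM gating threshold -- the anchor itself sits 30 μM below it, and a
calibration that parks the sensed value on the band edge would make the
qualitative gating outcome (half-open at slow ER diffusion, minimal at
fast) numerically fragile.  The optimum is 7 nm, the package default.

## Interpretation decisions

Several quantities in the source material admit more than one reading;
the package fixes each as follows.

* **"108 nm^3 volume".**  Read as a cube of edge 108 nm (1.26e6 nm³), not a
  volume of 108 nm³ (edge 4.8 nm).  The literal reading makes the sensed
  value a near-pore point sample far below the published 330 μM; the cube
  reading reproduces it.
* **Cytosolic Dirichlet placement.**  The model pins 30 nM on the lateral
  box faces (the drawn outer boundaries), not at the junction rim.  This
  matters quantitatively: with the box-face reading the junction
  communicates diffusively with 100 nm of surrounding cytosol before
  reaching the reservoir, and the five-ORAI junction-average amplitude
  converges to ~370 nM -- about 47% above the published 252 nM.  An
  independent axisymmetric finite-volume solve of the same problem
  confirms the 3D solver to <1% under this reading, and also shows that
  pinning 30 nM directly at the junction rim annulus yields ~230 nM,
  within 10% of the published value.  The published description of the
  cytosolic reservoir can be read either way; the rim reading, however,
  would also wall the junction off from IP3R-released Ca2+, contradicting
  the release-only control series, so the box-face reading is retained and
  the amplitude discrepancy is reported rather than tuned away.  Every other anchored quantity (pore
  peaks, ion budget, sensed averages, gating outcomes, SERCA bounds) is
  insensitive to this choice.
* **Residence time.**  Computed by Little's law: steady free-ion content of
  the junction divided by the channel influx in ions/s, ~1e-5 s for the
  five-ORAI scenario.  The published "order of 0.045 ms" is an
  order-of-magnitude statement whose method is not given; the Monte-Carlo
  first-exit oracle (`mc_residence_time()`) brackets the same order.  Both
  are reported; neither is forced to agree.
* **Spatial-extent threshold.**  The experimental microdomain
  classification threshold is not printed, so `spatial_extent()` takes the
  threshold as an explicit argument with no hidden default.
* **Which IP3Rs open.**  Presets open receptors in ascending index order
  around the ring (the choice affects only sub-percent asymmetries); the
  SERCA-operating-point preset selects the 4 nearest / 4 furthest
  receptors from the reference pump.

## What the scenarios do and do not emulate

The presets reproduce the study conditions: ORAI1-only series (1-5 open
channels), coupled IP3R+ORAI1 series (1-8 receptors, both \(D_S\) values),
the release-only control, clustered ORAI1 rings (37.7 vs 47 nm spacing)
and the SERCA operating points.  They do **not** emulate: cytosolic Ca2+
buffering, stochastic IP3R gating kinetics and Ca2+ feedback on the
receptor, explicit STIM molecules or their binding kinetics, membrane
potential / electro-diffusion, optical blurring of the microdomain, or
interactions between multiple junctions.  Passing tests therefore
demonstrate the deterministic, single-junction, buffer-free physics --
not a quantitative prediction for imaging data.

## Known limitations

* The stair-step representation of the cone wall limits the accuracy of
  quantities defined directly on that wall (IP3R mouth values) to a few
  percent at the default resolution; the junction average and the sensed
  cube averages are much less sensitive (tested to <2% under refinement).
* The gating fixed point is quasi-static in the transient mode (the open
  fraction follows the sensed average instantaneously), consistent with
  the pre-formed-complex assumption but not a kinetic STIM model.
* Pore-centre peaks combine an analytic self-term with a grid environment
  term; they are reported with the mesh level attached and should be
  compared across runs at equal resolution.
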