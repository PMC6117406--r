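---
title: "Transmural contractility and preserved ejection fraction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmural contractility and preserved ejection fraction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lvmech` simulates a single human left ventricle, idealized as a truncated
thick-walled ellipsoid, through one quasi-static beat, and asks a focused
physiological question: if the subendocardium stops contracting, how much
does the ejection fraction (EF) fall, and can a modest increase in
subepicardial contractility restore it? This is the mechanical core of the
hypothesis that heart failure with preserved ejection fraction (HFpEF) can
hide subendocardial dysfunction behind a compensating subepicardium. This
vignette documents the model, every tunable that matters, the numerical
choices, and what the tests do and do not establish.

## The subject and the geometry

All inputs are echocardiographic scalars of one normal adult: EDV = 53 ml,
EDP = 14.3 mmHg (from E/e' = 10 through the linear estimator
`EDP = 1.9 + 1.24 E/e'`), measured ESV = 24.8 ml, LV internal diameter
4.6 cm, posterior and septal wall thickness 0.9 cm. Diameter and thicknesses
are textbook normal values exposed as arguments of `paper_patient()`; the
measured volumes and pressure are fixed. `sample_patient()` draws synthetic
normal subjects from truncated normal distributions (EDV ~ N(53, 8) ml
truncated to [35, 80], E/e' ~ N(8, 2) on [4, 14], EF fraction ~ N(0.55,
0.05) on [0.40, 0.70], diameter ~ N(4.6, 0.3) cm, wall ~ N(0.9, 0.1) cm) so
the whole pipeline can be exercised across a plausible normal range; these
distributions emulate the marginal statistics of healthy echo reports, not
their correlations, and no diseased population is modeled.

The end-diastolic endocardium is a truncated ellipsoid of revolution whose
short-axis diameter equals the measured internal diameter and whose long
semi-axis is solved so the cavity volume equals EDV; the epicardium is
offset by the mean measured wall thickness. Two hard measurements (EDV and
diameter) fully determine the cavity proportions, so the aspect ratio is not
an independent dial: at 53 ml and 4.6 cm the cavity is necessarily short
relative to a textbook elongated LV. The basal plane sits at 0.4 of the
endocardial long semi-axis above the equator (`trunc_ratio`, a convention;
nothing downstream is sensitive to it at the +-0.1 level). The long axis is
z, the apex is the -z pole, the base plane is at z > 0.

The unloaded (stress-free) configuration is obtained by the single-point
regression `V0 = EDV (0.6 - 0.006 EDP)` = 27.25 ml: the endocardial surface
is scaled affinely to V0 and the epicardial scale is root-found so the wall
volume (69.7 ml here) is exactly preserved — affine scaling is used rather
than inverse finite-element unloading, matching the geometric character of
the construction.

### Mesh

The wall is meshed with trilinear hexahedra on a structured grid: exactly 8
transmural layers (layer 1 at the endocardium; layers 1–3, 4–5, 6–8 are the
subendocardial, midmyocardial and subepicardial regions), `n_circ`
circumferential and `n_long` longitudinal elements. The apical pole cannot
be covered by positive-Jacobian hexahedra in such a grid, so the mesh has a
small apical opening whose angular size shrinks as `n_long` grows; the
cavity surface is closed by flat apical and basal caps for volume tracking,
and ring-based measures (torsion) use the most apical complete node ring.
The faceted surface underestimates the continuum cavity volume (by ~2.5% at
16 circumferential elements); all volumes are reported in continuum units
through a fixed reference-state correction factor that cancels exactly in
EF and vanishes under refinement. Production runs use 8 x 16 x 10 = 1280
elements (4752 displacement unknowns), the passive fit uses 8 x 8 x 6;
these sizes were chosen as the coarsest grids whose EF changed by well under
a percentage point upon refinement of the calibration anchors.

### Fibers

Each element carries a local orthonormal triad (circumferential,
longitudinal, outward radial) built from the structured grid, and a fiber
direction rotated in the wall tangent plane by a helix angle that varies
linearly through the wall: +60 deg at the endocardial surface to -60 deg at
the epicardial surface, evaluated at element-centroid depth d = (layer -
0.5)/8. The sheet direction is the radial direction orthogonalized against
the fiber (transmural sheets), the most common rule-based choice; the sheet
and fiber-sheet passive terms then act across the wall.

## Material model

Passive stress derives from the Holzapfel–Ogden orthotropic energy with an
isochoric/volumetric split. The deviatoric part uses the isochoric
invariants (J^{-2/3}-scaled), which makes the reference configuration
exactly stress-free; the volumetric penalty is `(1/D)((J^2-1)/2 - ln J)`
with `D = 2/K` and K = 1 MPa by default (near-incompressibility; J stays
within a fraction of a percent in practice). The fiber and sheet
exponentials act only in tension (I4 > 1), the standard convention for
fiber-reinforced soft tissue. The default eight constants are the package's
reference human set (a = 6.832e-4 MPa, b = 7.541, a_f = 2.252e-3 MPa, b_f =
14.471, a_s = 3.127e-4 MPa, b_s = 12.548, a_fs = 1.837e-4 MPa, b_fs =
3.088); on this package's own geometry and mesh they are re-fitted before
use (below).

Active stress is a time-varying tension along the fiber added to the
passive second Piola–Kirchhoff stress as `T0(t, Eff)/I4f f0 (x) f0`, so the
Cauchy fiber stress has magnitude T0 lambda_f / J. The tension law has a
cosine rise to the peak at t0, a sarcomere-length-dependent relaxation
duration `tr = m l + b`, and length-dependent calcium sensitivity: `T0 =
Tmax Ca0^2 / (Ca0^2 + ECa50^2) Ct` with `ECa50 = Ca0max / sqrt(exp(B (l -
l0)) - 1)` and `l = lR sqrt(2 Eff + 1)`. Constants (`active_params()`):
Ca0 = Ca0max = 4.35 uM, B = 4.75 1/um, l0 = 1.58 um, lR = 1.85 um,
m = 1.0489 s/um, b = -1.429 s, t0 = 0.2 s — the established
cross-bridge-lineage defaults; they are config-exposed because the study
they descend from does not pin them, and EF outcomes are anchored against
their exact values by the ESV calibration. No cross-fiber active fraction
is included. `t_max` (MPa) is the contractility dial, assigned per region.

## Finite-element machinery

Total-Lagrangian 8-node hexahedra with 2x2x2 Gauss quadrature for the
deviatoric and active terms and single-point integration of the volumetric
penalty (the selective-reduced/mean-dilatation family), which avoids
volumetric locking at K = 1 MPa while keeping the consistent tangent exact.
Cavity pressure is applied as the conservative fluid-cavity load `F = p
dV/dx`, where V is the volume of the closed triangulated cavity surface
(wall facets plus caps); its tangent `p d2V/dx2` is symmetric, so the full
Newton matrix is symmetric and factorized by CHOLMOD supernodal Cholesky
through a persistent context (one symbolic analysis per model, numeric
refactorizations in place). Transient iterates under strong activation can
be genuinely indefinite; these are caught as factorization status codes and
handled by a Levenberg diagonal shift that escalates until the shifted
factorization succeeds. The resulting damped Newton steps are accepted as
search directions — convergence is always judged on the true force
residual, and the shift decays tenfold per successful iteration, restoring
the quadratic tail. If a damped iteration runs long without converging
(which happens when the converged state's own tangent is indefinite, e.g.
under extreme single-layer tension), the direction is upgraded to the
exact indefinite Newton step by preconditioned MINRES on the true tangent,
warm-started from the shifted solve; load-step bisection remains the outer
safeguard. The cavity-pressure unknown of
volume-controlled and afterload-coupled phases is eliminated by a rank-one
Schur complement so the sparse factorization never sees a dense row.

Boundary conditions follow the standard idealized-LV setup: basal nodes are
fixed longitudinally, and the mean in-plane translation and mean long-axis
rotation of the endocardial annulus are constrained (quadratic penalty,
stiffness 1e5; residual ring motions stay below 1e-6 cm), which removes all
rigid-body modes while letting the annulus dilate freely. Newton iterations
converge to a relative force residual of 1e-8 (volume constraints to 1e-6
ml); steps are capped at 0.8 cm and failed steps are bisected up to eight
times. Assembly order is deterministic, so identical configurations
reproduce bitwise-identical results.

## One beat

* **Diastole**: cavity pressure is ramped to EDP through a staircase
  (with small warm-up sub-steps near the very soft reference state),
  recording the passive PV curve.
* **Isovolumic contraction**: activation time starts at 0; volume is held
  at EDV (|dV| <= 0.1 ml, achieved to 1e-6 ml) with pressure as the
  unknown, in increments of `dt` (default 0.01 s, i.e. 80 increments over a
  nominal 0.8 s beat), until the cavity pressure reaches the aortic opening
  pressure.
* **Ejection**: the ventricle is coupled to a two-element Windkessel
  (opening/initial arterial pressure 80 mmHg, resistance R, compliance C);
  the implicit-Euler afterload balance `C dp/dt + p/R = -dV/dt` is solved
  monolithically with equilibrium at each increment. End systole is the
  first increment at which the outflow would reverse (valve closure); ESV
  and ESP are read there. If the peak isovolumic pressure never reaches the
  opening pressure the beat is flagged no-ejection with ESV = EDV.
  Arterial pressure is held at its initial value during the brief
  isovolumic phase (its runoff decay over ~0.1 s is a 3% effect).

## Calibration

* **Passive fit.** The model's ED PV curve is matched to the single-point
  Klotz EDPVR (An = 28.2 mmHg, Bn = 2.79, V0 from the unloading regression;
  the curve interpolates the measured (53 ml, 14.3 mmHg) point exactly) by
  least squares on cavity volumes at 8 evenly spaced pressures in (0, EDP]
  — volume mismatch at matched pressures is robust where the curve is steep
  in V. Stage one rescales the four stiffness scales by a common factor
  (secant on V(EDP)); stage two frees all eight constants within bounds
  (a-type in [1e-6, 1e-1] MPa on a log scale, b-type in [0.1, 30]) under
  box-constrained quasi-Newton iteration. The eight-parameter problem is
  non-unique, so the fit is judged by curve mismatch (RMS <= 2% of EDV),
  never by parameter equality. The fit runs on the coarse mesh; a final
  common-factor polish on the production mesh lands V(EDP) on the measured
  EDV to 0.05 ml, and the parameters are then frozen for all scenarios.
* **Afterload freeze.** R is rescaled (at most twice, with T_max
  re-calibrated after each update) until the baseline ESP is within 2 mmHg
  of 88.9 mmHg; C stays at 2.5 ml/mmHg. The afterload is then frozen so
  that scenario differences emerge from mechanics, not from re-tuning.
* **Contractility.** Uniform baseline T_max is root-found (bracketed false
  position with the Illinois acceleration; ESV is monotone in T_max) until
  ESV matches the measured 24.8 ml within 0.15 ml. Scenario 3 repeats the
  root-find on the subepicardial T_max alone, with the subendocardium
  silent and the midmyocardium at baseline. Because the length-dependent
  activation drives tension to zero as sarcomeres shorten toward `l0`,
  ESV(T_max) saturates at a floor; if the target lies below that floor the
  scenario-3 recalibration returns the saturation point, flagged
  `saturated = TRUE`, rather than failing the study.

## The six scenarios

With geometry, passive parameters, activation timing and afterload shared,
only the per-region T_max triple changes: (1) uniform baseline; (2)
subendocardium zero; (3) subendocardium zero, subepicardium recalibrated to
the baseline ESV; (4) all layers halved; (5) only the subendocardium
active; (6) subepicardium zero. Reported per scenario: EF, ESV, ESP,
normalized torsion `(phi_apex - phi_base)(rho_apex + rho_base)/(2D)` in
degrees (ring rotations positive counterclockwise seen from the apex,
evaluated ES-relative-to-ED on the apical and annulus rings), global
longitudinal/circumferential/radial strains, the ES sphericity index
(cavity long-axis length over maximal short-axis diameter), and transmural
profiles of fiber strain and total Cauchy fiber stress per layer.

Strain conventions: global strains and transmural fiber-strain profiles are
reported relative to the **end-diastolic** configuration (volume-weighted
Green–Lagrange components in the element-local reference basis), the
clinical convention that makes the signs comparable with echo strain;
profiles also carry the unloaded-reference fiber strain for diagnostics.
Strain values are interpreted by sign and ordering, not by equality.

On the production mesh the study lands at (scenario: EF): 1: 53.4%, 2:
39.6%, 3: 42.1%, 4: 45.5%, 5: 16.7%, 6: 41.2%, with baseline T_max
0.185 MPa. Two features deserve comment. First, the compensation of
scenario 3 is partial: with the subendocardium silent, ESV saturates near
31 ml however hard the subepicardium is driven (30.7 ml at three times the
baseline T_max), because the fibers of the remaining layers shorten into
the zero-tension sarcomere length before the cavity reaches the baseline
ESV. Second, EF responds shallowly to uniform contractility changes
(halving T_max costs only ~8 EF points) for the same reason read in the
opposite direction: the baseline calibration already operates deep in the
length-saturated regime. Both trace to the geometry: holding EDV = 53 ml,
an internal diameter of 4.6 cm and a 0.9 cm wall forces a near-spherical
cavity, which demands more fiber shortening per milliliter ejected than a
prolate ventricle, and the length-dependent activation devalues tension
exactly at end systole where it is needed. The transmural signatures are
unaffected: silencing the subendocardium drops EF by ~14 points, raises
torsion, and leaves the silenced layers at near-zero ED-referenced
systolic fiber strain, while silencing the outer layers reverses the
torsion sign.

## Numerical choices and degenerate inputs

Tolerances: Newton 1e-8 relative force residual; volume constraint 1e-6
ml; ESV calibration 0.15 ml; passive-fit EDV polish 0.05 ml. Exponent
overflow in the constitutive law (exponents > 60) and inverted elements
signal step rejection rather than crashing, and trigger bisection. A
contractility target equal to EDV short-circuits to T_max = 0; a baseline
target below the saturation floor raises a calibration error, while the
scenario-3 recalibration degrades to the flagged saturation point as
described above. Zero-pressure
inflation returns the reference state exactly. EDP >= 100 mmHg is rejected
by the unloading regression (non-physical factor), E/e' <= 0 by the
filling-pressure estimator, and wall thickness at or beyond the cavity
radius by the geometry builder.

## What the tests show, and what they do not

The test suite verifies the mechanics against independent oracles (energy
finite differences, dense-algebra invariants, tet-decomposition volumes, an
incompressible thick-sphere closed form, R-side shape-function integrals
for affine patch states), the calibration anchors (EF = 53.2% by
construction once ESV hits 24.8 +- 0.2 ml), and the qualitative transmural
signatures (EF ordering across scenarios, torsion increase under
subendocardial silencing and reversal under outer-layer silencing, tensile
subendocardial fiber strain, sphericity shifts). Quantities that are not
pinned by the calibration anchors — scenario-wise ESP values, exact torsion
and strain magnitudes — are tracked
by direction and ordering only. Passing tests establish internal
consistency and reproduction of the study's mechanics on an idealized
single-subject geometry; they do not validate the model against independent
clinical populations, image-derived anatomies, diastolic dysfunction, or
electrophysiological activation sequences, all of which are out of scope.

## Known limitations

The ventricle is a single idealized LV without atria, right ventricle,
valves, or activation sequence (timing is homogeneous by assumption); the
afterload is a two-element Windkessel rather than a closed-loop
circulation, so ESP differences across scenarios are qualitative; the
sarcomere-level constants of the active law are literature defaults, and
the ESV calibration absorbs their uncertainty into T_max — T_max values
should therefore be compared between scenarios, not read as absolute tissue
properties. The apical opening of the structured mesh is a geometric
compromise; apical fields within one element ring of the opening should not
be over-interpreted.
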