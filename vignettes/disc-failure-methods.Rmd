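---
title: "Methods: a finite-element failure analysis of the ovine lumbar disc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a finite-element failure analysis of the ovine lumbar disc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`discfem` rebuilds, as a tested R package, a finite-element analysis of
intervertebral-disc failure under combined loads: a parametric model of an
ovine lumbar (L3--4 scale) disc with an anisotropic hyperelastic annulus
fibrosus, quasi-static simulation of flexion / lateral bending / axial
rotation / compression scenarios, regional tensile-stress extraction, a
weighted damage score for experimental failure counts, and regression- and
threshold-based failure-risk prediction. This vignette documents the model,
its numerical treatment, the deliberate design decisions, and what the test
suite does and does not establish.

## The mechanical model

### Geometry

The disc is generated parametrically (`build_disc_mesh()`): the cross-section
contour is a superellipse $|x/a|^p + |y/b|^p = 1$ through the configured
lateral width (30 mm) and antero-posterior depth (22 mm); the annulus height
interpolates linearly from 4.5 mm anteriorly to 2.5 mm posteriorly; thin
cartilaginous endplates (CEP, 0.1 mm) cap the nucleus and inner annulus and
bony endplates (BEP, 0.5 mm) cap the whole disc. The nucleus occupies a
configurable area fraction (default 0.40) of the cross-section, its centroid
shifted slightly posteriorly (default 5% of depth). The mesh is a structured
"butterfly" pattern of 8-node hexahedra: a central block, transition rings
filling the nucleus, and annulus rings, extruded through
BEP/CEP/core/CEP/BEP layers. The default resolution gives 1248 elements,
within the coarse-model band the analyses are designed for.

Because the original model's CT-derived endplate outline, lamellar fiber
angles and nucleus boundary are not published, three geometric choices are
deliberately parametric rather than fitted: the superellipse exponent
(default 2.5), the fiber inclination (default $\pm 30^\circ$ to the local
circumferential direction, the conventional lamellar value, configurable per
annulus region), and the nucleus offset. Each annulus element carries two
unit fiber vectors, mirror images across the circumferential axis, and a
right-handed local (circumferential, radial, axial) frame derived from the
contour tangent; all regional stresses are reported in that frame.

### Materials

Three behaviors (`disc_materials()` reproduces the published parameter
table):

* **Annulus fibrosus** (anterior / lateral / posterior parameter sets): a
  dispersed two-fiber-family hyperelastic solid,
  $$\Psi = c_{10}(\bar I_1 - 3) + \frac{1}{d}\Big(\frac{J^2-1}{2} - \ln J\Big)
    + \frac{k_1}{2k_2}\sum_{\alpha=1,2}
      \Big(e^{k_2 \langle \bar E_\alpha\rangle^2} - 1\Big),$$
  with $\bar E_\alpha = \kappa(\bar I_1 - 3) + (1-3\kappa)(\bar I_{4\alpha}-1)$
  and the Macaulay bracket switching the fiber term off when the dispersed
  fiber strain is compressive. This is the standard dispersed-fiber
  convention matching a $(C_{10}, D, K_1, K_2, \kappa)$ parameter tuple; the
  exact volumetric convention of the source model is not published, so the
  $\frac{1}{d}(\frac{J^2-1}{2}-\ln J)$ form of the commercial solver family
  it was built in is adopted (a documented, not verifiable, choice).
* **Nucleus pulposus**: the same form without fibers (Neo-Hookean matrix
  plus volumetric term).
* **Endplates** ("linear elastic" $E$, $\nu$): implemented as a compressible
  Neo-Hookean solid with the matching Lame constants,
  $\Psi = \frac{\mu}{2}(I_1-3) - \mu\ln J + \frac{\lambda}{2}(\ln J)^2$.
  This reduces exactly to Hooke's law in the small-strain limit (the tangent
  at the identity is the exact Hooke operator) while remaining monotone in
  compression. A Saint Venant--Kirchhoff implementation was tried first and
  rejected: its compressive softening instability quasi-statically crushed
  the 0.1 mm CEP layer in the combined load cases.

### Swelling initialization

The nucleus is pre-pressurized before loading (`initialize_swelling()`): an
isotropic swelling eigenstretch $F = \lambda_s F_e$ is applied to the NP
elements and its magnitude found by a secant root solve (warm-started
equilibrium solves) so that the volume-averaged NP hydrostatic pressure
$-\mathrm{tr}(\sigma)/3$, with the disc otherwise unloaded, meets the 0.2 MPa
target within tolerance (default 5%). The observable (mean pressure) is
prescribed rather than an osmotic mechanism, because only the observable is
reported for the source model; "initial NP pressure" is read as the volume
mean, the other plausible readings (peak, pore pressure) being unavailable
in a hyperelastic model.

### Boundary conditions and loading

The caudal surface is fixed in all degrees of freedom. The cranial surface
is kinematically coupled to a reference node at its centroid: rotations are
prescribed there, the transverse translations are fixed, and the axial
translation is force-controlled (free, carrying the 800 N compressive dead
load when active, zero force otherwise). Two conventions the source text
does not state are fixed here and exposed as code: the axial force is a
*dead* load along the global axis (not a follower load), and all active
rotation components are composed into a *single rotation vector* ramped
simultaneously with the force, which makes the result independent of any
application order. The built-in registry (`scenario_registry()`) encodes the
five complex scenarios (800 N / 4 deg axial rotation / 10 deg lateral
bending / 13 deg flexion, with one component removed per case) and the ten
simple scenarios. The printed source table marks its "AC + AR" simple
scenario with rotation only; the registry encodes compression + rotation as
the name says and offers `paper_literal = TRUE` to reproduce the printed
row.

## Numerical treatment

* **Element technology.** Trilinear hexahedra with the F-bar treatment of
  the volumetric response (element-average $J$ substituted at every Gauss
  point) against locking at near-incompressibility. The internal force is
  the *exact gradient* of the element energy including the $\bar J$ coupling
  terms; the variationally inconsistent shortcut (standard B-matrix with
  F-bar stress) was observed to pump energy into the explicit dynamics and
  destabilize thin endplate elements, and is not used.
* **Implicit solver.** Newton iteration on the reduced system (free
  degrees of freedom plus the rigid axial translation), sparse LU via
  `Matrix`, element stiffness by forward finite differencing of the analytic
  internal force, residual-based backtracking line search (the exponential
  fiber stiffening makes full Newton steps overshoot from slack states), and
  automatic increment cutting to 1/64 of the base increment.
* **Explicit solver.** Damped central-difference dynamic relaxation with
  adaptive mass scaling (per-element stiffness estimates refreshed
  periodically; safety factor on the stable step) and a smooth cosine load
  ramp followed by a settling hold. The kinetic and internal (strain)
  energies are recorded along the run; `kinetic_energy_ratio()` reports the
  maximum of kinetic over total energy, the quasi-static acceptance
  criterion (< 10%). The rigid axial degree of freedom receives
  near-critical damping: it is far slower than the element modes, and the
  global velocity damping alone lets it overshoot and crush thin layers.
* **Hybrid strategy.** Disc-scale scenario runs use the explicit ramp
  followed by a Newton *polish* at full load, combining the robustness of
  dynamic relaxation (the source analyses used an explicit code) with
  implicit-quality residuals. If an element inverts on the dynamic path --
  it happens only for the all-loads case on the coarse mesh, where the
  anterior-lateral nucleus corner is pinched at about 96% load -- the solver
  backs off to 0.85 times the failure load factor, re-runs the ramp there,
  and continues to full load by incremental implicit Newton.
* **Overflow guard.** The fiber exponential argument $k_2\bar E^2$ is
  continued linearly above 60. Converged states sit at arguments of order
  one; the guard only keeps transient trial states finite.
* **Averaging conventions.** "Tensile stress" is the Macaulay-positive part
  of the local-frame normal component, volume-averaged over the *full*
  subsection volume (the alternative, averaging only over tensile elements,
  sits behind `positive_only = TRUE`). The interface stress divides the
  transmitted axial nodal forces by the *current* (deformed) patch area, so
  a uniform true stress field reproduces itself exactly.

## Analysis sections

Three annulus sectors are analysed (plus an anterior sector): POST spans
$\pm 20^\circ$ about the posterior midline; POST-LAT1 and POST-LAT2 are the
adjacent $25^\circ$ sectors on the tension side of the lateral bend. The
published figure showing this layout is schematic, so the angular extents
are configurable (`section_bounds()`). Each sector splits into six
subsections: axial thirds (cranial / middle / caudal) by the element's
normalized column height, radial halves (inner / outer) by annulus-thickness
fraction. Scenario-ordering checks are evaluated on the POST-LAT1 averaged
tensile axial stress, the exact quantity of the source's case-by-case
comparison; the pure-load "< 4 MPa" bound is evaluated on the POST section,
from whose figures that statement derives.

## The synthetic specimen generator

`simulate_specimens()` emulates the parallel in vitro study (six specimens
per scenario, large/small annulus and endplate-junction failures scored 1
and 0.5): each failure type is an independent Bernoulli draw with
probability $\mathrm{logit}^{-1}((\sigma - \text{location})/\text{scale})$
of a chosen stress predictor. The logistic link is a modeling choice (the
source implies monotone risk via thresholds but no probability model); the
default locations (22--28 MPa) and scales (4 MPa) were calibrated once
against the coarse-mesh POST-LAT2 axial stress scale of the built-in
scenarios so that failure probabilities are high for the highest-stress
cases and near zero for the no-flexion case, and never revisited.

What the generator does *not* emulate: within-scenario stress variability
(all specimens of a scenario share one FE prediction, as in the source
study, leaving five distinct design points -- a documented limitation of the
regression), correlation between failure modes, and the experimental
distinction between cases 1 and 2. On that last point the model is
informative: every stress measure puts the no-compression case marginally
*above* the all-loads case (compression is carried by the nucleus and even
slightly relieves annulus tension), so no stress-monotone failure process
can reproduce the strict experimental score ordering between those two
cases; the attainable and tested property is that the flexion-bearing cases
dominate case 4, which dominates the no-flexion case 5.

## What a green test suite establishes (and what it does not)

The suite verifies: constitutive correctness (energy--stress--tangent
consistency by finite differences, objectivity, the tension-only fiber
switch, exact Hooke limit); mesh integrity (printed dimensions exactly,
positive Jacobians, volume conservation under refinement, determinism);
solver correctness on fixtures (single-element states matching the point
model to $10^{-8}$, an exact patch test, global force balance to $10^{-6}$,
implicit/explicit agreement within 2%); the full pipeline on the default
coarse mesh (0.2 MPa swelling within 5%, the < 10% kinetic-energy criterion
for case 5, the pure-load POST-section bound, scenario ordering, significant
axial and circumferential predictors); and the statistics layer against
closed-form OLS and binomial oracles.

It does **not** establish quantitative agreement with the published
full-resolution stress magnitudes (for example the 12 MPa axial level of
the all-loads cases). The published model has 56,496 elements and calibrated
fiber angles that are not recoverable from the text; the coarse default mesh
overestimates postero-lateral averages by roughly a factor of two. The
package therefore claims the *property-level* results (orderings, bounds,
thresholds, significance patterns), not the field values. Two further
honest caveats. First, the implicit solver can converge to unstable
equilibria (a slender compressed fixture converges straight, while the
explicit dynamics correctly buckles it -- the modes are compared only on
stable states). Second, the mesh-convergence study for case 5
(`analysis/06_mesh_convergence.R`, outside the test suite for runtime
reasons) shows the coarse meshes are *not* in the asymptotic regime for
field values: refining a 384-element disc to 2048 elements changes the
POST-section mean axial stress by about 19%, and the refinement of the
default mesh exceeds desktop runtime. The original study's convergence
statement concerns its 56,496-element mesh, which this package supports but
does not require; at desk scale only orderings, bounds and thresholds are
claimed, and the convergence study documents exactly why.

## Known limitations

No viscoelasticity or poroelasticity (the source model is hyperelastic); no
interlamellar radial fibers; no vertebral bodies or posterior elements; no
contact; one generic geometry rather than subject-specific shapes; failure
is scored, not simulated (no damage evolution). The regression layer
reports per-predictor significance without multiplicity correction by
default, matching the source's reporting; Benjamini--Hochberg adjustment
and a joint multiple-regression mode are available behind flags.
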