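# discfem

Finite-element failure analysis of the ovine lumbar intervertebral disc
under complex loads, as a tested R package.

## The problem

Which mechanical condition is unsafe for an intervertebral disc? Combined
flexion, lateral bending, axial rotation and compression can tear the
annulus fibrosus (AFF) or the endplate junction (EPJF), but single-load
experiments disagree about the culprit. `discfem` rebuilds a workflow that
answers the question by combining a nonlinear finite-element model of an
ovine lumbar disc with the failure counts of a parallel in vitro study:
simulate the loading scenarios, average the tensile stresses where failures
occur, score the experimental damage, and ask which predicted stresses are
predictive of the damage score — turning stress levels into failure-risk
thresholds.

It is aimed at spine-biomechanics researchers who want a transparent,
scriptable re-implementation of this class of analysis: every stage — mesh
generation, constitutive model, solvers, post-processing, statistics — is an
exported, unit-tested R function (with the numerical kernel in C++).

## The model in brief

* Parametric hexahedral disc mesh: superellipse cross-section (width 30 mm,
  depth 22 mm), annulus height 4.5 mm anterior to 2.5 mm posterior,
  cartilaginous (0.1 mm) and bony (0.5 mm) endplates, nucleus at 40% of the
  cross-section; two fiber families at ±30° to the circumferential direction
  in each annulus element.
* Annulus fibrosus: dispersed-fiber anisotropic hyperelasticity,

  Ψ = C₁₀(Ī₁−3) + (1/D)((J²−1)/2 − ln J)
      + (K₁/2K₂) Σ_α [exp(K₂⟨Ē_α⟩²) − 1],
  Ē_α = κ(Ī₁−3) + (1−3κ)(Ī₄α−1),

  with region-specific parameters (anterior/lateral/posterior); Neo-Hookean
  nucleus; linear elastic endplates (exact Hooke limit).
* Nucleus swelling initialisation to a mean pressure of 0.2 MPa, caudal
  fixation, kinematic coupling of the cranial endplate to a reference node
  carrying prescribed rotations and an 800 N axial dead load.
* Quasi-static solution by explicit dynamic relaxation (kinetic energy kept
  below 10% of total) with an implicit Newton polish, or by incremental
  implicit Newton; F-bar hexahedra against volumetric locking.
* Post-processing: volume-averaged tensile stresses per annulus sector
  (POST, POST-LAT1, POST-LAT2, ANT) × six subsections × direction
  (axial/circumferential/radial), annulus–endplate interface stress, damage
  score S = LargeEPJF + 0.5·SmallEPJF + LargeAFF + 0.5·SmallAFF,
  per-predictor OLS of score on stress, and risk classification
  (axial 10/6 MPa, circumferential 9/6 MPa, interface 3.5 MPa thresholds).

## Worked example

Score the packaged in vitro failure counts and classify a stress level:

```r
library(discfem)
counts <- invitro_failure_counts()
damage_score(counts)
#> [1] 12.0  8.5  7.5  4.5  0.0
classify_risk(c(12, 8, 4), "axial")
#> [1] "high"     "moderate" "low"
```

Run one loading scenario end to end on the small verification disc
(~500 elements; the default mesh has 1248):

```r
mesh <- make_fixture("mini-disc")
mats <- disc_materials()
swell <- initialize_swelling(mesh, mats)
round(swell$np_pressure, 4)
#> [1] 0.2
res <- run_scenario("FL", mesh = mesh, materials = mats,
                    cfg = solver_config(mode = "explicit-relaxation",
                                        explicit_steps = 16000),
                    prestate = swell)
subset(res$stresses, section == "POST" & subset == "all")
#>     section subset       direction    value   volume     risk
#> 142    POST    all           axial 9.322290 85.56797 moderate
#> 143    POST    all circumferential 6.222185 85.56797 moderate
#> 144    POST    all          radial 2.401477 85.56797     <NA>
```

The swelling step hits the 0.2 MPa nucleus pressure target (printed value
0.1999); pure flexion then loads the posterior annulus to an averaged
tensile axial stress of about 9 MPa on this very coarse fixture — between
the low-risk (6 MPa) and high-risk (10 MPa) thresholds, hence `moderate`:
flexion alone already approaches the unsafe range, which is the central
qualitative finding this workflow reproduces. (The ~500-element fixture is
deliberately minimal; some of its subsections are empty and flagged by
warnings, and its averages run higher than the default 1248-element mesh.)

The numbered drivers under `analysis/` walk the full study on the default
mesh: geometry checks, swelling, the five complex and ten simple scenario
batteries, the stress-vs-score regression, a mesh-convergence study and a
synthetic-specimen power study, writing tables under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the damage scores of
the packaged failure-count table; the volume-averaged nucleus pressure after
swelling initialisation on the default coarse mesh; the maximum
kinetic-to-total energy ratio of the explicit run of the
compression+rotation+bending scenario; and the largest POST-section mean
tensile stress over the pure compression, rotation and bending scenarios.
It writes them as a JSON object and takes roughly 10 minutes on one CPU.

## Package layout

* `R/`, `src/` — geometry, materials, constitutive model (R reference +
  C++ kernel), solvers, sectioning, failure statistics, synthetic data,
  exporters (VTU / FE deck / CSV / JSON).
* `tests/testthat/` — unit, property and acceptance tests.
* `analysis/` — numbered narrative drivers.
* `vignettes/disc-failure-methods.Rmd` — the methods vignette: model,
  assumptions, numerical choices, design decisions, limitations.
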