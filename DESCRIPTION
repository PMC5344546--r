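Package: discfem
Title: Finite-Element Failure Analysis of the Ovine Lumbar Intervertebral Disc
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric hexahedral finite-element model of an ovine lumbar
    intervertebral disc with an anisotropic hyperelastic (Holzapfel-Gasser-Ogden)
    annulus fibrosus, a nearly incompressible Neo-Hookean nucleus pulposus and
    linear elastic endplates. Provides nucleus swelling initialisation, implicit
    Newton and explicit dynamic-relaxation quasi-static solvers for combined
    flexion, lateral bending, axial rotation and compression load cases, regional
    tensile-stress averaging in local circumferential/radial/axial frames,
    annulus-endplate interface stress, damage scoring of experimental failure
    counts, stress-versus-score regression and threshold-based failure-risk
    classification, plus a synthetic specimen generator for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
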