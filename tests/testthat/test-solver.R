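# Quasi-static solver: constitutive consistency, patch test, coupling,
# equilibrium, implicit/explicit agreement, kinetic-energy bookkeeping.

test_that("single-element homogeneous state matches the constitutive oracle", {
  fx <- make_fixture("single-element")
  mats <- block_mats(neo_hookean_params(0.16779, 0.12))
  lam <- 0.95
  bot <- which(abs(fx$nodes[, 3]) < 1e-9)
  top <- which(abs(fx$nodes[, 3] - 1) < 1e-9)
  bnd <- list(prescribed = rbind(
    data.frame(node = bot, dof = 3, value = 0),
    data.frame(node = top, dof = 3, value = lam - 1),
    data.frame(node = 1, dof = 1, value = 0),
    data.frame(node = 1, dof = 2, value = 0),
    data.frame(node = 2, dof = 2, value = 0)))
  st <- solve_quasi_static(fx, mats, boundary = bnd,
                           cfg = solver_config(increments = 4, tol = 1e-10))
  # oracle: homogeneous uniaxial-stress state of the point model
  f0 <- function(lat) cauchy_stress(
    deformation_state(diag(c(lat, lat, lam))), mats$block)[1, 1]
  lat <- stats::uniroot(f0, c(0.9, 1.2), tol = 1e-14)$root
  sig <- cauchy_stress(deformation_state(diag(c(lat, lat, lam))), mats$block)
  expect_equal(st$stress[1, 3], sig[3, 3], tolerance = 1e-8)
  expect_equal(st$stress[1, 1], 0, tolerance = 1e-10)
})

test_that("patch test: affine boundary displacements give an exactly uniform field", {
  px <- make_fixture("patch-block")
  mats <- block_mats(linear_elastic_params(24, 0.4))
  A <- matrix(c(0.001, 0.0004, 0, 0.0002, -0.0006, 0.0003,
                0.0001, 0, 0.0008), 3, 3)
  bdry <- which(apply(px$nodes, 1, function(x)
    any(abs(x) < 1e-9 | abs(x - 1) < 1e-9)))
  disp <- px$nodes[bdry, ] %*% t(A)
  presc <- data.frame(node = rep(bdry, 3), dof = rep(1:3, each = length(bdry)),
                      value = as.vector(disp))
  st <- solve_quasi_static(px, mats, boundary = list(prescribed = presc),
                           cfg = solver_config(increments = 1, tol = 1e-12))
  expect_lt(max(apply(st$stress, 2, function(cc) diff(range(cc)))), 1e-10)
  sig <- cauchy_stress(deformation_state(diag(3) + A), mats$block)
  expect_equal(st$stress[1, ], c(sig[1, 1], sig[2, 2], sig[3, 3],
                                 sig[1, 2], sig[2, 3], sig[1, 3]),
               tolerance = 1e-10)
})

test_that("zero load on the mini-disc yields zero displacement and stress", {
  md <- make_fixture("mini-disc")
  lc0 <- load_case(axial_force = 0,
                   active = c(compression = TRUE, axial_rotation = FALSE,
                              lateral_bending = FALSE, flexion = FALSE))
  st <- solve_quasi_static(md, disc_materials(), load = lc0,
                           cfg = solver_config(increments = 1))
  expect_lt(max(abs(st$u)), 1e-10)
  expect_lt(max(abs(st$stress)), 1e-10)
})

test_that("global equilibrium: caudal reaction balances the applied axial force", {
  md <- make_fixture("mini-disc")
  lc <- load_case(axial_force = 100,
                  active = c(compression = TRUE, axial_rotation = FALSE,
                             lateral_bending = FALSE, flexion = FALSE))
  st <- solve_quasi_static(md, disc_materials(), load = lc,
                           cfg = solver_config(increments = 2))
  expect_equal(abs(st$reaction[3]), 100, tolerance = 1e-6)
})

test_that("kinematic coupling is rigid and order-independent", {
  md <- make_fixture("mini-disc")
  rot <- c(-13, 10, 4) * pi / 180
  coup <- apply_coupling(md, rot, 0)
  X <- md$nodes[coup$coupled, ]
  disp <- discfem:::coupled_rigid_disp(md, coup, 1)
  x1 <- X + disp
  idx <- seq(1, nrow(X), length.out = 15)
  d0 <- dist(X[idx, ]); d1 <- dist(x1[idx, ])
  expect_lt(max(abs(d1 - d0)), 1e-9)
  # pure translation moves all coupled nodes identically (tz dof direction)
  # and the single-rotation-vector composition is order-free by construction:
  # it differs from either sequential application by at most |w1||w2|r/2
  R12 <- discfem:::rotation_matrix(rot)
  Ra <- discfem:::rotation_matrix(c(rot[1], 0, 0)) %*%
    discfem:::rotation_matrix(c(0, rot[2], rot[3]))
  Rb <- discfem:::rotation_matrix(c(0, rot[2], rot[3])) %*%
    discfem:::rotation_matrix(c(rot[1], 0, 0))
  r <- sweep(X, 2, coup$xref)
  lever <- max(sqrt(rowSums(r^2)))
  bound <- abs(rot[1]) * sqrt(rot[2]^2 + rot[3]^2) * lever
  expect_lt(max(abs(r %*% t(R12) - r %*% t(Ra))), bound)
  expect_lt(max(abs(r %*% t(R12) - r %*% t(Rb))), bound)
  # empty coupled set is a configuration error
  md2 <- md; md2$node_sets$cranial_coupled <- integer(0)
  expect_error(apply_coupling(md2), "configuration")
})

test_that("implicit and explicit modes agree on the bar fixture within 2%", {
  bar <- make_fixture("tension-bar")
  mats <- block_mats(neo_hookean_params(0.16779, 0.12))
  lc <- load_case(axial_force = 0.03,
                  active = c(compression = TRUE, axial_rotation = FALSE,
                             lateral_bending = FALSE, flexion = FALSE))
  sti <- solve_quasi_static(bar, mats, load = lc,
                            cfg = solver_config(increments = 2))
  ste <- solve_quasi_static(bar, mats, load = lc,
                            cfg = solver_config(mode = "explicit-relaxation",
                                                explicit_steps = 2000,
                                                explicit_hold = 2000,
                                                damping = 0.05,
                                                mass_update = 20,
                                                polish = FALSE))
  expect_equal(ste$stress[5, 3], sti$stress[5, 3], tolerance = 0.02)
  # and on the single element
  se <- make_fixture("single-element")
  sti2 <- solve_quasi_static(se, mats, load = lc,
                             cfg = solver_config(increments = 2))
  ste2 <- solve_quasi_static(se, mats, load = lc,
                             cfg = solver_config(mode = "explicit-relaxation",
                                                 explicit_steps = 2000,
                                                 explicit_hold = 2000,
                                                 damping = 0.05,
                                                 mass_update = 20,
                                                 polish = FALSE))
  expect_equal(ste2$stress[1, 3], sti2$stress[1, 3], tolerance = 0.02)
})

test_that("kinetic energy ratio: zero history gives 0; implicit mode errors", {
  st <- structure(list(mode = "explicit-relaxation",
                       energy_history = data.frame(
                         step = 0:2, s = c(0, 0.5, 1),
                         kinetic = c(0, 0, 0), internal = c(0, 1, 2))),
                  class = "solution_state")
  expect_equal(kinetic_energy_ratio(st), 0)
  sti <- structure(list(mode = "implicit-newton"), class = "solution_state")
  expect_error(kinetic_energy_ratio(sti), "not applicable")
})

test_that("halving the loading rate does not increase the kinetic-energy ratio", {
  # self-equilibrated (externally unloaded) prestate via an eigenstretch in
  # the middle of the bar, mirroring how the swelling prestate enters the
  # disc scenarios; the energy ratio then scales like rate^2
  bar <- make_fixture("tension-bar")
  mats <- block_mats(neo_hookean_params(0.16779, 0.12))
  swell <- rep(1, 10); swell[4:7] <- 1.03
  lc0 <- load_case(axial_force = 0,
                   active = c(compression = TRUE, axial_rotation = FALSE,
                              lateral_bending = FALSE, flexion = FALSE))
  pre <- solve_quasi_static(bar, mats, load = lc0, swell = swell,
                            ramp_swell = TRUE,
                            cfg = solver_config(increments = 2))
  lc <- load_case(axial_force = 0.04,
                  active = c(compression = TRUE, axial_rotation = FALSE,
                             lateral_bending = FALSE, flexion = FALSE))
  ratios <- vapply(c(1500, 3000), function(n) {
    st <- solve_quasi_static(bar, mats, load = lc, prestate = pre,
                             cfg = solver_config(mode = "explicit-relaxation",
                                                 explicit_steps = n,
                                                 explicit_hold = 1000,
                                                 damping = 0.05,
                                                 mass_update = 20,
                                                 polish = FALSE))
    kinetic_energy_ratio(st)
  }, 0)
  expect_lte(ratios[2], ratios[1] * 1.0 + 1e-9)
})

test_that("unconvergeable loading fails with a solver-failure error", {
  se <- make_fixture("single-element")
  mats <- block_mats(neo_hookean_params(0.16779, 0.12))
  lc <- load_case(flexion = 170, axial_force = 0,
                  active = c(compression = FALSE, axial_rotation = FALSE,
                             lateral_bending = FALSE, flexion = TRUE))
  expect_error(
    solve_quasi_static(se, mats, load = lc,
                       cfg = solver_config(increments = 2, max_iterations = 8)),
    "solver failure")
})
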