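#' Deformation state at a material point
#'
#' @param f 3x3 deformation gradient with positive determinant.
#' @param fiber_dirs Optional list of one or two unit reference fiber
#'   direction vectors (required for anisotropic materials).
#' @return A `deformation_state` object.
#' @export
deformation_state <- function(f, fiber_dirs = NULL) {
  f <- as.matrix(f)
  stopifnot(is.numeric(f), all(dim(f) == c(3, 3)))
  if (!(det(f) > 0)) stop("kinematics error: det(f) must be positive")
  if (!is.null(fiber_dirs)) {
    fiber_dirs <- lapply(fiber_dirs, as.numeric)
    for (a in fiber_dirs) {
      if (length(a) != 3 || abs(sqrt(sum(a^2)) - 1) > 1e-8)
        stop("fiber directions must be unit 3-vectors")
    }
  }
  structure(list(f = f, fiber_dirs = fiber_dirs), class = "deformation_state")
}

check_fibers <- function(state, params) {
  if (inherits(params, "aniso_hyper_params") &&
      (is.null(state$fiber_dirs) || length(state$fiber_dirs) < 2))
    stop("configuration error: anisotropic material requires two fiber directions")
}

# Isochoric kinematic quantities shared by the decoupled materials.
iso_kin <- function(state) {
  f <- state$f
  j <- det(f)
  fbar <- j^(-1 / 3) * f
  bbar <- fbar %*% t(fbar)
  h <- lapply(state$fiber_dirs, function(a) as.numeric(fbar %*% a))
  list(j = j, fbar = fbar, bbar = bbar, i1b = sum(diag(bbar)), h = h)
}

# Fiber response: dispersed strain, first and second energy derivatives.
# The exponential argument is continued linearly above 60 (overflow guard far
# outside the physical range; identical to the compiled kernel).
fiber_terms <- function(kin, params) {
  k1 <- params$k1; k2 <- params$k2; kap <- params$kappa
  lapply(kin$h, function(h) {
    i4b <- sum(h^2)
    eb <- kap * (kin$i1b - 3) + (1 - 3 * kap) * (i4b - 1)
    active <- eb > 0
    arg <- k2 * eb^2
    ex <- if (arg <= 60) exp(arg) else exp(60) * (1 + (arg - 60))
    dex <- if (arg <= 60) ex else exp(60)
    list(h = h, i4b = i4b, eb = eb, active = active,
         psi = if (active) (k1 / (2 * k2)) * (ex - 1) else 0,
         fE = if (active) k1 * eb * dex else 0,            # d psi / d Ebar
         gE = if (active) {                                # d2 psi / d Ebar2
           if (arg <= 60) k1 * (1 + 2 * k2 * eb^2) * ex else k1 * exp(60)
         } else 0)
  })
}

#' Strain energy density
#'
#' Energy per unit reference volume (MPa) for the three supported material
#' behaviors. Zero at the identity (and at any rigid rotation); the fiber
#' term contributes only when the dispersed fiber strain is tensile.
#'
#' @param state A [deformation_state()].
#' @param params A `material_params` object.
#' @return Scalar energy density (MPa).
#' @export
strain_energy <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "material_params"))
  check_fibers(state, params)
  if (inherits(params, "linear_elastic_params")) {
    lm <- lame_constants(params)
    f <- state$f
    lnj <- log(det(f))
    i1 <- sum(f * f)
    return(0.5 * lm[["mu"]] * (i1 - 3) - lm[["mu"]] * lnj +
             0.5 * lm[["lambda"]] * lnj^2)
  }
  kin <- iso_kin(state)
  psi <- params$c10 * (kin$i1b - 3) +
    ((kin$j^2 - 1) / 2 - log(kin$j)) / params$d
  if (inherits(params, "aniso_hyper_params"))
    psi <- psi + sum(vapply(fiber_terms(kin, params), `[[`, 0, "psi"))
  as.numeric(psi)
}

#' Cauchy (true) stress
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress tensor (MPa).
#' @export
cauchy_stress <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "material_params"))
  check_fibers(state, params)
  if (inherits(params, "linear_elastic_params")) {
    lm <- lame_constants(params)
    f <- state$f; j <- det(f)
    tau <- lm[["mu"]] * (f %*% t(f)) +
      (lm[["lambda"]] * log(j) - lm[["mu"]]) * diag(3)
    return(tau / j)
  }
  kin <- iso_kin(state)
  taubar <- 2 * params$c10 * kin$bbar
  if (inherits(params, "aniso_hyper_params")) {
    kap <- params$kappa
    for (ft in fiber_terms(kin, params)) {
      if (!ft$active) next
      taubar <- taubar + 2 * ft$fE * kap * kin$bbar +
        2 * ft$fE * (1 - 3 * kap) * outer(ft$h, ft$h)
    }
  }
  p <- (kin$j - 1 / kin$j) / params$d
  tau <- taubar - mean(diag(taubar)) * diag(3) + kin$j * p * diag(3)
  tau / kin$j
}

# --- fourth-order tensor helpers (arrays dim c(3,3,3,3)) --------------------

dyad22 <- function(a, b) outer(a, b)                    # A_ij B_kl
sym4 <- function(a, b) {                                # 1/2(A_ik B_jl + A_il B_jk)
  out <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    out[i, j, k, l] <- 0.5 * (a[i, k] * b[j, l] + a[i, l] * b[j, k])
  out
}
tens_contract <- function(a, b) {
  # (A:B)_ijmn = A_ijkl B_klmn
  array(matrix(a, 9, 9) %*% matrix(b, 9, 9), c(3, 3, 3, 3))
}

#' Material tangent operator
#'
#' Fourth-order tangent `dsigma/depsilon`: the derivative of the Cauchy
#' stress under a superposed small symmetric strain increment
#' `F -> (I + eps) F`, including the geometric stress terms. It possesses
#' the minor symmetries exactly; the major symmetry holds in the stress-free
#' limit (and for linear elastic parameters at the identity the operator is
#' exactly Hooke's).
#'
#' @inheritParams strain_energy
#' @return Array of dimension `c(3, 3, 3, 3)` (MPa).
#' @export
material_tangent <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "material_params"))
  check_fibers(state, params)
  id <- diag(3)
  i4s <- sym4(id, id)
  sig <- cauchy_stress(state, params)
  j <- det(state$f)

  if (inherits(params, "linear_elastic_params")) {
    lm <- lame_constants(params)
    lnj <- log(det(state$f))
    cc <- lm[["lambda"]] * dyad22(id, id) +
      2 * (lm[["mu"]] - lm[["lambda"]] * lnj) * i4s
  } else {
    kin <- iso_kin(state)
    pdev <- i4s - dyad22(id, id) / 3
    p <- (kin$j - 1 / kin$j) / params$d
    pprime <- (1 + 1 / kin$j^2) / params$d
    cc_vol <- kin$j * (p + kin$j * pprime) * dyad22(id, id) -
      2 * kin$j * p * i4s
    taubar <- 2 * params$c10 * kin$bbar
    ccbar <- array(0, c(3, 3, 3, 3))
    if (inherits(params, "aniso_hyper_params")) {
      kap <- params$kappa
      for (ft in fiber_terms(kin, params)) {
        if (!ft$active) next
        m <- outer(ft$h, ft$h)
        taubar <- taubar + 2 * ft$fE * kap * kin$bbar +
          2 * ft$fE * (1 - 3 * kap) * m
        ccbar <- ccbar + 4 * (
          kap^2 * ft$gE * dyad22(kin$bbar, kin$bbar) +
          kap * (1 - 3 * kap) * ft$gE *
            (dyad22(kin$bbar, m) + dyad22(m, kin$bbar)) +
          (1 - 3 * kap)^2 * ft$gE * dyad22(m, m))
      }
    }
    devt <- taubar - mean(diag(taubar)) * id
    cc_iso <- tens_contract(tens_contract(pdev, ccbar), pdev) +
      (2 / 3) * sum(diag(taubar)) * pdev -
      (2 / 3) * (dyad22(devt, id) + dyad22(id, devt))
    cc <- cc_vol + cc_iso
    j <- kin$j
  }

  geom <- sym4(id, sig) + sym4(sig, id) - dyad22(sig, id)
  cc / j + geom
}
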