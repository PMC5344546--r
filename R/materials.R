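#' Anisotropic hyperelastic (Holzapfel-Gasser-Ogden) parameters
#'
#' Parameter set for a dispersed two-fiber-family soft tissue: an isochoric
#' Neo-Hookean matrix term `c10*(I1bar - 3)`, a volumetric term
#' `(1/d)*((J^2-1)/2 - log(J))` and an exponential fiber term
#' `(k1/(2*k2)) * sum_a (exp(k2 * <Ebar_a>^2) - 1)` with dispersed fiber
#' strain `Ebar_a = kappa*(I1bar-3) + (1-3*kappa)*(I4bar_a - 1)` and a
#' Macaulay bracket that switches the fiber term off in compression.
#'
#' @param c10 Matrix shear-like coefficient (MPa), positive.
#' @param d Volumetric compliance coefficient (1/MPa), positive.
#' @param k1 Fiber stiffness (MPa), non-negative.
#' @param k2 Fiber exponential coefficient (dimensionless), positive.
#' @param kappa Fiber dispersion parameter in [0, 1/3].
#' @return An object of class `aniso_hyper_params`.
#' @export
aniso_hyper_params <- function(c10, d, k1, k2, kappa) {
  stopifnot(is.numeric(c10), c10 > 0, is.numeric(d), d > 0,
            is.numeric(k1), k1 >= 0, is.numeric(k2), k2 > 0,
            is.numeric(kappa), kappa >= 0, kappa <= 1/3)
  structure(list(c10 = c10, d = d, k1 = k1, k2 = k2, kappa = kappa),
            class = c("aniso_hyper_params", "material_params"))
}

#' Neo-Hookean parameters
#'
#' Nearly incompressible Neo-Hookean material: `c10*(I1bar-3)` plus the same
#' volumetric term as [aniso_hyper_params()].
#'
#' @param c10 Shear-like coefficient (MPa), positive.
#' @param d Volumetric compliance coefficient (1/MPa), positive.
#' @return An object of class `neo_hookean_params`.
#' @export
neo_hookean_params <- function(c10, d) {
  stopifnot(is.numeric(c10), c10 > 0, is.numeric(d), d > 0)
  structure(list(c10 = c10, d = d),
            class = c("neo_hookean_params", "material_params"))
}

#' Linear elastic parameters
#'
#' Implemented as a compressible Neo-Hookean solid with the matching Lame
#' constants (objective at finite rotation, exactly Hooke's law in the
#' small-strain limit, monotone resistance under compression), which is how
#' the thin endplate layers are treated inside the finite-deformation
#' pipeline.
#'
#' @param e Young's modulus (MPa), positive.
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @return An object of class `linear_elastic_params`.
#' @export
linear_elastic_params <- function(e, nu) {
  stopifnot(is.numeric(e), e > 0, is.numeric(nu), nu > -1, nu < 0.5)
  structure(list(e = e, nu = nu),
            class = c("linear_elastic_params", "material_params"))
}

#' Lame constants of a linear elastic parameter set
#' @param params A `linear_elastic_params` object.
#' @return Named vector with `lambda` and `mu` (MPa).
#' @export
lame_constants <- function(params) {
  stopifnot(inherits(params, "linear_elastic_params"))
  e <- params$e; nu <- params$nu
  c(lambda = e * nu / ((1 + nu) * (1 - 2 * nu)), mu = e / (2 * (1 + nu)))
}

#' Default disc material set
#'
#' Region-keyed constitutive parameters for the ovine lumbar disc model:
#' anisotropic hyperelastic annulus (anterior/lateral/posterior), Neo-Hookean
#' nucleus and linear elastic cartilaginous/bony endplates.
#'
#' @return Named list keyed by region label (`AF-anterior`, `AF-lateral`,
#'   `AF-posterior`, `NP`, `CEP-cranial`, `CEP-caudal`, `BEP-cranial`,
#'   `BEP-caudal`), each a `material_params` object.
#' @export
disc_materials <- function() {
  cep <- linear_elastic_params(24, 0.4)
  bep <- linear_elastic_params(1000, 0.3)
  list(
    "AF-anterior"  = aniso_hyper_params(0.06046, 0.311,  24, 1700, 0.01),
    "AF-lateral"   = aniso_hyper_params(0.0327,  0.6154,  5,  940, 0.01),
    "AF-posterior" = aniso_hyper_params(0.0772,  0.2609,  1,   50, 0.01),
    "NP"           = neo_hookean_params(0.16779, 0.12),
    "CEP-cranial"  = cep, "CEP-caudal" = cep,
    "BEP-cranial"  = bep, "BEP-caudal" = bep
  )
}

# Encode a material_params object for the C++ kernel:
# list(type = int, params = numeric(5)).
encode_material <- function(params) {
  if (inherits(params, "aniso_hyper_params")) {
    list(type = 0L, params = c(params$c10, params$d, params$k1, params$k2,
                               params$kappa))
  } else if (inherits(params, "neo_hookean_params")) {
    list(type = 1L, params = c(params$c10, params$d, 0, 0, 0))
  } else if (inherits(params, "linear_elastic_params")) {
    lm <- lame_constants(params)
    list(type = 2L, params = c(lm[["lambda"]], lm[["mu"]], 0, 0, 0))
  } else {
    stop("unknown material parameter class")
  }
}

# Per-element material arrays for a mesh + region-keyed material list.
material_arrays <- function(mesh, materials) {
  regions <- mesh$region
  missing <- setdiff(unique(regions), names(materials))
  if (length(missing) > 0)
    stop("no material parameters for region(s): ", paste(missing, collapse = ", "))
  ne <- length(regions)
  mtype <- integer(ne)
  mpar <- matrix(0, ne, 5)
  enc <- lapply(materials, encode_material)
  for (rg in unique(regions)) {
    idx <- which(regions == rg)
    mtype[idx] <- enc[[rg]]$type
    mpar[idx, ] <- matrix(enc[[rg]]$params, length(idx), 5, byrow = TRUE)
  }
  aniso <- mtype == 0L
  if (any(aniso)) {
    f1 <- mesh$fiber1; f2 <- mesh$fiber2
    if (is.null(f1) || any(is.na(f1[aniso, ])))
      stop("anisotropic material assigned to elements without fiber directions")
  }
  f1 <- if (is.null(mesh$fiber1)) matrix(0, ne, 3) else mesh$fiber1
  f2 <- if (is.null(mesh$fiber2)) matrix(0, ne, 3) else mesh$fiber2
  f1[is.na(f1)] <- 0; f2[is.na(f2)] <- 0
  list(mtype = mtype, mpar = mpar, fib1 = f1, fib2 = f2)
}
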