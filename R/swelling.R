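#' Swelling configuration
#'
#' @param target_np_pressure Target volume-averaged nucleus hydrostatic
#'   pressure (MPa), non-negative; default 0.2.
#' @param tolerance Relative tolerance on the achieved mean pressure.
#' @param max_iterations Secant iterations of the eigenstretch root solve.
#' @param increments Load increments of each equilibrium solve.
#' @return A `swelling_config` object.
#' @export
swelling_config <- function(target_np_pressure = 0.2, tolerance = 0.05,
                            max_iterations = 10, increments = 4) {
  stopifnot(target_np_pressure >= 0, tolerance > 0, max_iterations >= 1)
  structure(list(target_np_pressure = target_np_pressure,
                 tolerance = tolerance, max_iterations = max_iterations,
                 increments = increments),
            class = "swelling_config")
}

#' Mean nucleus pressure of a solution
#'
#' Volume-weighted mean of the hydrostatic pressure `-trace(sigma)/3` over
#' the nucleus elements (reference-volume weights).
#'
#' @param state A `solution_state`.
#' @param mesh The mesh the state was computed on.
#' @return Scalar pressure (MPa), positive in compression.
#' @export
np_mean_pressure <- function(state, mesh) {
  idx <- which(mesh$region == "NP")
  if (length(idx) == 0) stop("mesh has no NP elements")
  p <- -(state$stress[idx, 1] + state$stress[idx, 2] + state$stress[idx, 3]) / 3
  sum(p * mesh$volumes[idx]) / sum(mesh$volumes[idx])
}

#' Initialize the nucleus swelling pre-stress
#'
#' Establishes the initial nucleus pressurization before load application:
#' an isotropic swelling eigenstretch is applied to the NP elements and its
#' magnitude found by a secant root solve so that, with the disc otherwise
#' unloaded (caudal endplate fixed, cranial endplate coupled with free axial
#' translation and zero force), the equilibrated volume-averaged NP
#' hydrostatic pressure matches the target. The mechanism prescribes the
#' observable (mean pressure) rather than an osmotic model.
#'
#' @param mesh A `disc_mesh`.
#' @param materials Region-keyed material list.
#' @param cfg A [swelling_config()].
#' @param solver A [solver_config()] for the equilibrium solves.
#' @return A `solution_state` with the converged swelling field (`swell`),
#'   the achieved mean NP pressure (`np_pressure`) and the eigenstretch
#'   (`swell_stretch`).
#' @export
initialize_swelling <- function(mesh, materials, cfg = swelling_config(),
                                solver = solver_config()) {
  stopifnot(inherits(mesh, "disc_mesh"), inherits(cfg, "swelling_config"))
  np <- mesh$region == "NP"
  zero_load <- load_case(axial_force = 0, axial_rotation = 0,
                         lateral_bending = 0, flexion = 0,
                         active = c(compression = TRUE, axial_rotation = FALSE,
                                    lateral_bending = FALSE, flexion = FALSE))
  solver$increments <- cfg$increments

  if (cfg$target_np_pressure == 0) {
    ne <- nrow(mesh$hexes)
    st <- structure(list(u = numeric(3 * nrow(mesh$nodes)), tz = 0,
                         stress = matrix(0, ne, 6), energy = 0,
                         mode = "implicit-newton", swell = rep(1, ne),
                         reaction = c(0, 0, 0), converged = TRUE),
                    class = "solution_state")
    st$np_pressure <- 0; st$swell_stretch <- 1
    return(st)
  }

  warm <- NULL
  run <- function(lambda) {
    sw <- rep(1, nrow(mesh$hexes)); sw[np] <- lambda
    if (is.null(warm)) {
      st <- solve_quasi_static(mesh, materials, load = zero_load, cfg = solver,
                               swell = sw, ramp_swell = TRUE)
    } else {
      # warm start: previous equilibrium is an excellent initial guess for a
      # nearby eigenstretch, so solve directly at full swelling
      cfg1 <- solver; cfg1$increments <- 1
      st <- solve_quasi_static(mesh, materials, load = zero_load, cfg = cfg1,
                               prestate = warm, swell = sw, ramp_swell = FALSE)
    }
    st$np_pressure <- np_mean_pressure(st, mesh)
    st$swell_stretch <- lambda
    warm <<- st
    st
  }

  # secant from (1, 0) and a confined-compression-based first guess
  target <- cfg$target_np_pressure
  dnp <- if (inherits(materials$NP, "neo_hookean_params")) materials$NP$d else 0.12
  l0 <- 1; p0 <- 0
  l1 <- 1 + target * dnp / 4
  st <- run(l1); p1 <- st$np_pressure
  for (i in seq_len(cfg$max_iterations)) {
    if (abs(p1 - target) <= 0.25 * cfg$tolerance * target) break
    if (abs(p1 - p0) < 1e-12) break
    l2 <- l1 + (target - p1) * (l1 - l0) / (p1 - p0)
    l2 <- max(1 + 1e-6, l2)
    l0 <- l1; p0 <- p1; l1 <- l2
    st <- run(l1); p1 <- st$np_pressure
  }
  if (abs(p1 - target) > cfg$tolerance * target)
    stop("solver failure: swelling equilibration missed the target pressure (",
         signif(p1, 4), " vs ", target, " MPa)")
  st
}
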