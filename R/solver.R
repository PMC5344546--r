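#' Load case definition
#'
#' Combined quasi-static load: prescribed rotations about the three anatomic
#' axes applied through a reference node kinematically coupled to the cranial
#' endplate, plus an axial dead force. Components ramp simultaneously
#' (composed as a single rotation vector), so the result does not depend on
#' an application order. Sign conventions: flexion tips the cranial plate
#' anteriorly, lateral bending lowers the +x side, axial rotation is
#' right-handed about the spine axis.
#'
#' @param axial_force Compressive axial force (N, positive = compression).
#' @param axial_rotation,lateral_bending,flexion Rotation magnitudes
#'   (degrees, non-negative).
#' @param active Named logical vector switching components on/off
#'   (`compression`, `axial_rotation`, `lateral_bending`, `flexion`).
#' @return A `load_case` object.
#' @export
load_case <- function(axial_force = 800, axial_rotation = 4,
                      lateral_bending = 10, flexion = 13,
                      active = c(compression = TRUE, axial_rotation = TRUE,
                                 lateral_bending = TRUE, flexion = TRUE)) {
  stopifnot(axial_force >= 0, axial_rotation >= 0, lateral_bending >= 0,
            flexion >= 0)
  need <- c("compression", "axial_rotation", "lateral_bending", "flexion")
  if (!all(need %in% names(active)))
    stop("active flags must name ", paste(need, collapse = ", "))
  active <- active[need]
  if (!any(active)) stop("at least one load component must be active")
  structure(list(axial_force = axial_force, axial_rotation = axial_rotation,
                 lateral_bending = lateral_bending, flexion = flexion,
                 active = active),
            class = "load_case")
}

# Effective rotation vector (radians) and axial force of a load case.
load_effective <- function(load) {
  d2r <- pi / 180
  rot <- c(
    -(if (load$active[["flexion"]]) load$flexion else 0) * d2r,
    (if (load$active[["lateral_bending"]]) load$lateral_bending else 0) * d2r,
    (if (load$active[["axial_rotation"]]) load$axial_rotation else 0) * d2r)
  force <- if (load$active[["compression"]]) load$axial_force else 0
  list(rotvec = rot, force = force)
}

#' Solver configuration
#'
#' @param mode `"implicit-newton"` (default) or `"explicit-relaxation"`.
#' @param tol Relative residual tolerance of the implicit solver.
#' @param max_iterations Newton iterations per increment.
#' @param increments Base number of load increments (implicit).
#' @param explicit_steps Ramp steps of the explicit dynamic relaxation.
#' @param explicit_hold Settling steps at full load after the ramp.
#' @param damping Per-step velocity damping fraction of the explicit mode.
#' @param record_every Energy-history recording interval (steps).
#' @param mass_safety Mass-scaling safety factor (explicit stability).
#' @param mass_update Steps between mass-matrix re-estimations.
#' @param polish Follow the explicit relaxation with a Newton polish at full
#'   load (cleans the residual to implicit tolerance; the energy history of
#'   the dynamic phase is kept).
#' @return A `solver_config` object.
#' @export
solver_config <- function(mode = c("implicit-newton", "explicit-relaxation"),
                          tol = 1e-6, max_iterations = 30, increments = 8,
                          explicit_steps = 6000, explicit_hold = 2000,
                          damping = 0.05, record_every = 20,
                          mass_safety = 1.6, mass_update = 100,
                          polish = TRUE) {
  mode <- match.arg(mode)
  stopifnot(tol > 0, increments >= 1, max_iterations >= 1,
            explicit_steps >= 10, damping > 0, damping < 1)
  structure(list(mode = mode, tol = tol, max_iterations = max_iterations,
                 increments = increments, explicit_steps = explicit_steps,
                 explicit_hold = explicit_hold, damping = damping,
                 record_every = record_every, mass_safety = mass_safety,
                 mass_update = mass_update, polish = polish),
            class = "solver_config")
}

#' Kinematic coupling constraint set
#'
#' Ties the cranial node set rigidly to a reference node at the centroid of
#' the cranial surface: each coupled node displaces by the reference
#' translation plus the finite-rotation action on its lever arm. The axial
#' translation of the reference node is force-controlled (free); transverse
#' translations are fixed; rotations are prescribed.
#'
#' @param mesh A `disc_mesh` (uses `node_sets$cranial_coupled` and
#'   `node_sets$caudal_fixed`).
#' @param rotation Rotation vector (radians) applied at full load.
#' @param force Axial dead force (N, compression positive).
#' @return A `coupling` object (fixed set, coupled set, reference point,
#'   rotation vector, force).
#' @export
apply_coupling <- function(mesh, rotation = c(0, 0, 0), force = 0) {
  coupled <- mesh$node_sets$cranial_coupled
  if (is.null(coupled) || length(coupled) == 0)
    stop("configuration error: empty cranial coupled node set")
  xref <- colMeans(mesh$nodes[coupled, , drop = FALSE])
  structure(list(fixed = mesh$node_sets$caudal_fixed, coupled = coupled,
                 xref = xref, rotvec = as.numeric(rotation),
                 force = force, free_tz = TRUE),
            class = "coupling")
}

rotation_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

# Rigid displacement of the coupled nodes at load factor s (without tz).
coupled_rigid_disp <- function(mesh, coup, s) {
  R <- rotation_matrix(coup$rotvec * s)
  r0 <- sweep(mesh$nodes[coup$coupled, , drop = FALSE], 2, coup$xref)
  r0 %*% t(R) - r0
}

assemble <- function(mesh, arrays, swell, u, want_K = FALSE,
                     want_stress = FALSE, fd_h = 1e-6) {
  cpp_assemble(mesh$nodes, mesh$hexes, arrays$mtype, arrays$mpar,
               arrays$fib1, arrays$fib2, swell, u, want_K, want_stress, fd_h)
}

#' Quasi-static solution of the nonlinear equilibrium problem
#'
#' Implicit mode: Newton iteration with a residual line search, load
#' incrementation and automatic increment cutting (down to 1/64 of the base
#' increment). Explicit mode: damped central-difference dynamic relaxation
#' with adaptive mass scaling, recording the kinetic/internal energy history
#' used by [kinetic_energy_ratio()], followed by a Newton polish at full
#' load (see `polish` in [solver_config()]); if an element inverts on the
#' dynamic path, the solver backs off to 0.85 times the failure load factor
#' and continues to full load by incremental implicit Newton
#' (`explicit_scale` in the result records the hand-over point).
#'
#' Loading is either a [load_case()] applied through [apply_coupling()]
#' (disc meshes) or a generic `boundary` list for verification fixtures:
#' `fixed` (node ids clamped in all dofs), `prescribed` (data.frame
#' `node`, `dof`, `value`, ramped) and optional `forces` (same columns,
#' ramped dead loads).
#'
#' @param mesh A `disc_mesh` or fixture mesh.
#' @param materials Region-keyed list of `material_params`.
#' @param load A [load_case()] or `NULL`.
#' @param cfg A [solver_config()].
#' @param prestate Optional `solution_state` (e.g. from
#'   [initialize_swelling()]) supplying the initial displacement and the
#'   nucleus swelling field, held constant while the load ramps.
#' @param boundary Optional generic boundary conditions (see above).
#' @param swell Optional per-element eigenstretch vector; ramped with the
#'   load factor when `ramp_swell` is `TRUE`.
#' @param ramp_swell Ramp the swelling field with the load factor.
#' @return A `solution_state`: displacements, per-element mean Cauchy stress
#'   (global frame), energies, reaction force, convergence log.
#' @export
solve_quasi_static <- function(mesh, materials, load = NULL,
                               cfg = solver_config(), prestate = NULL,
                               boundary = NULL, swell = NULL,
                               ramp_swell = FALSE) {
  arrays <- material_arrays(mesh, materials)
  nn <- nrow(mesh$nodes); ndof <- 3 * nn; ne <- nrow(mesh$hexes)

  swell_final <- if (!is.null(swell)) swell
    else if (!is.null(prestate) && !is.null(prestate$swell)) prestate$swell
    else rep(1, ne)
  if (length(swell_final) == 1) swell_final <- rep(swell_final, ne)
  u0 <- if (!is.null(prestate)) prestate$u else numeric(ndof)

  coup <- NULL
  if (!is.null(load)) {
    eff <- load_effective(load)
    coup <- apply_coupling(mesh, eff$rotvec, eff$force)
  }
  if (is.null(coup) && is.null(boundary))
    stop("either a load case or boundary conditions must be given")

  ## ---- constraint machinery (shared by both modes) --------------------------
  role <- rep(0L, nn) # 0 free, 1 fixed, 2 coupled
  presc <- NULL; forces <- NULL
  if (!is.null(coup)) {
    role[coup$fixed] <- 1L
    role[coup$coupled] <- 2L
  } else {
    if (!is.null(boundary$fixed)) role[boundary$fixed] <- 1L
    presc <- boundary$prescribed
    forces <- boundary$forces
  }
  dof_of <- function(node, dof) 3L * (node - 1L) + dof
  fixed_dofs <- integer(0)
  if (any(role == 1L))
    fixed_dofs <- as.vector(outer(1:3, which(role == 1L),
                                  function(d, n) dof_of(n, d)))
  presc_dofs <- integer(0); presc_vals <- numeric(0)
  if (!is.null(presc) && nrow(presc) > 0) {
    presc_dofs <- dof_of(presc$node, presc$dof)
    presc_vals <- presc$value
  }
  coup_nodes <- if (!is.null(coup)) coup$coupled else integer(0)
  coup_dofs <- if (length(coup_nodes))
    as.vector(outer(1:3, coup_nodes, function(d, n) dof_of(n, d))) else integer(0)

  constrained <- c(fixed_dofs, presc_dofs, coup_dofs)
  free_dofs <- setdiff(seq_len(ndof), constrained)
  nfree <- length(free_dofs)
  has_tz <- !is.null(coup) && coup$free_tz
  nred <- nfree + as.integer(has_tz)

  # transformation u_full = T q + g(s)
  ti <- free_dofs; tj <- seq_len(nfree); tx <- rep(1, nfree)
  if (has_tz) {
    zdofs <- dof_of(coup_nodes, 3L)
    ti <- c(ti, zdofs); tj <- c(tj, rep(nred, length(zdofs)))
    tx <- c(tx, rep(1, length(zdofs)))
  }
  Tm <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, nred))

  gvec <- function(s) {
    g <- numeric(ndof)
    if (!is.null(coup)) {
      gd <- coupled_rigid_disp(mesh, coup, s)
      g[dof_of(coup_nodes, 1L)] <- gd[, 1]
      g[dof_of(coup_nodes, 2L)] <- gd[, 2]
      g[dof_of(coup_nodes, 3L)] <- gd[, 3]
    }
    if (length(presc_dofs)) g[presc_dofs] <- s * presc_vals
    g
  }
  fext_red <- function(s) {
    fe <- numeric(nred)
    if (has_tz) fe[nred] <- -s * coup$force
    if (!is.null(forces) && nrow(forces) > 0) {
      fd <- dof_of(forces$node, forces$dof)
      full <- numeric(ndof); full[fd] <- s * forces$value
      fe <- fe + as.numeric(Matrix::crossprod(Tm, full))
    }
    fe
  }
  swell_at <- function(s) if (ramp_swell) 1 + s * (swell_final - 1) else swell_final

  # Newton iteration (with backtracking line search: exponential fiber
  # stiffening makes the full step overshoot from slack states) at fixed
  # load factor s.
  it_total <- 0
  newton_at <- function(q, s, maxit = cfg$max_iterations) {
    g_s <- gvec(s)
    fe_s <- fext_red(s)
    u_try <- as.numeric(Tm %*% q) + g_s
    for (it in seq_len(maxit)) {
      asm <- assemble(mesh, arrays, swell_at(s), u_try, want_K = TRUE)
      if (!asm$ok || !is.finite(asm$energy)) return(list(ok = FALSE, q = q))
      r_red <- as.numeric(Matrix::crossprod(Tm, asm$fint)) - fe_s
      ref <- max(1e-3, sqrt(sum(asm$fint[constrained]^2)),
                 if (has_tz) abs(s * coup$force) else 0)
      rn <- sqrt(sum(r_red^2))
      it_total <<- it_total + 1
      if (rn <= cfg$tol * ref)
        return(list(ok = TRUE, q = q, iterations = it, residual = rn))
      K <- Matrix::sparseMatrix(i = asm$Ki + 1L, j = asm$Kj + 1L, x = asm$Kx,
                                dims = c(ndof, ndof))
      Kr <- Matrix::crossprod(Tm, K %*% Tm)
      dq <- tryCatch(as.numeric(Matrix::solve(Kr, -r_red)),
                     error = function(e) NULL)
      if (is.null(dq) || any(!is.finite(dq))) return(list(ok = FALSE, q = q))
      alpha <- 1; accepted <- FALSE
      for (ls in 1:10) {
        u_ls <- as.numeric(Tm %*% (q + alpha * dq)) + g_s
        a2 <- assemble(mesh, arrays, swell_at(s), u_ls, want_K = FALSE)
        if (a2$ok && is.finite(a2$energy)) {
          r2 <- sqrt(sum((as.numeric(Matrix::crossprod(Tm, a2$fint)) - fe_s)^2))
          if (r2 < (1 - 0.05 * alpha) * rn) { accepted <- TRUE; break }
        }
        alpha <- alpha / 2
      }
      if (!accepted) return(list(ok = FALSE, q = q))
      q <- q + alpha * dq
      u_try <- as.numeric(Tm %*% q) + g_s
    }
    list(ok = FALSE, q = q)
  }

  finish <- function(q, mode, extra = list()) {
    u_full <- as.numeric(Tm %*% q) + gvec(1)
    fin <- assemble(mesh, arrays, swell_at(1), u_full, want_stress = TRUE)
    fixed_nodes <- which(role == 1L)
    reaction <- vapply(1:3, function(d)
      sum(fin$fint[dof_of(fixed_nodes, d)]), 0)
    structure(c(list(
      u = u_full, tz = if (has_tz) q[nred] else NA_real_,
      stress = fin$sigma, energy = fin$energy, mode = mode,
      swell = swell_at(1), reaction = reaction,
      iterations = it_total, converged = TRUE), extra),
      class = "solution_state")
  }

  # initial reduced coordinates from u0
  q <- numeric(nred)
  q[seq_len(nfree)] <- u0[free_dofs]
  if (has_tz && length(coup_nodes)) q[nred] <- mean(u0[dof_of(coup_nodes, 3L)])

  # incremental Newton continuation from load factor s0 to 1
  continue_implicit <- function(q, s0) {
    s_done <- s0; ds <- max((1 - s0) / cfg$increments, 1e-4)
    ds_base <- ds; ds_min <- ds / 64
    log_rows <- list()
    while (s_done < 1 - 1e-12) {
      s_try <- min(1, s_done + ds)
      res <- newton_at(q, s_try)
      if (res$ok) {
        q <- res$q; s_done <- s_try
        log_rows[[length(log_rows) + 1]] <-
          data.frame(s = s_done, ds = ds, iterations = res$iterations)
        ds <- min(2 * ds, ds_base)
      } else {
        ds <- ds / 2
        if (ds < ds_min)
          stop("solver failure: no convergence at load factor ",
               signif(s_done, 4), " (increment cut below 1/64 of base)")
      }
    }
    list(q = q, log = do.call(rbind, log_rows))
  }

  if (cfg$mode == "explicit-relaxation") {
    if (is.null(coup))
      stop("explicit mode supports load-case (coupled) boundary conditions")
    if (ramp_swell)
      stop("explicit mode expects the swelling field as a fixed prestate")
    run_explicit <- function(scale, nsteps) {
      cpp_explicit(mesh$nodes, mesh$hexes, arrays$mtype, arrays$mpar,
                   arrays$fib1, arrays$fib2, swell_final, u0,
                   as.integer(coup$fixed), as.integer(coup$coupled),
                   coup$xref, coup$rotvec * scale, coup$force * scale,
                   coup$free_tz, as.integer(nsteps),
                   as.integer(cfg$explicit_hold), cfg$damping,
                   as.integer(cfg$record_every), cfg$mass_safety,
                   as.integer(cfg$mass_update))
    }
    scale <- 1
    res <- run_explicit(1, cfg$explicit_steps)
    if (!res$ok) {
      # element inverted on the dynamic path: back off to a safe fraction of
      # the load and hand over to implicit continuation
      s_fail <- 0.5 * (1 - cos(pi * res$bad_step / cfg$explicit_steps))
      scale <- max(0.25, 0.85 * min(s_fail, 1))
      res <- run_explicit(scale, as.integer(ceiling(cfg$explicit_steps * scale)))
      if (!res$ok)
        stop("kinematics error: element ", res$bad_elem,
             " inverted during explicit relaxation (step ", res$bad_step, ")")
    }
    q[seq_len(nfree)] <- res$u[free_dofs]
    if (has_tz) q[nred] <- res$tz
    polished <- FALSE
    if (scale < 1) {
      pol <- newton_at(q, scale, maxit = max(25, cfg$max_iterations))
      if (pol$ok) q <- pol$q
      cont <- continue_implicit(q, scale)
      q <- cont$q
      polished <- TRUE
    } else if (isTRUE(cfg$polish)) {
      pol <- newton_at(q, 1, maxit = max(25, cfg$max_iterations))
      if (pol$ok) { q <- pol$q; polished <- TRUE }
    }
    return(finish(q, "explicit-relaxation", extra = list(
      energy_history = data.frame(step = res$step, s = res$s * scale,
                                  kinetic = res$ke, internal = res$ie,
                                  tz = res$tz_hist, min_jacobian = res$minj_hist),
      residual_free = res$residual_free, reaction_norm = res$reaction_norm,
      explicit_scale = scale, polished = polished)))
  }

  ## ---- incremental implicit Newton ------------------------------------------
  cont <- continue_implicit(q, 0)
  finish(cont$q, "implicit-newton", extra = list(convergence = cont$log))
}

#' Maximum kinetic-to-total energy ratio (%)
#'
#' Quasi-static acceptance check of an explicit dynamic-relaxation run: the
#' maximum over the recorded history of kinetic energy as a percentage of
#' total (kinetic + internal) energy. A value below 10 is taken as
#' quasi-static, following the usual explicit-dynamics criterion.
#'
#' @param state A `solution_state` from the explicit mode.
#' @return Scalar percentage.
#' @export
kinetic_energy_ratio <- function(state) {
  stopifnot(inherits(state, "solution_state"))
  if (state$mode != "explicit-relaxation" || is.null(state$energy_history))
    stop("not applicable: kinetic energy history requires the explicit mode")
  h <- state$energy_history
  tot <- h$kinetic + h$internal
  ratio <- ifelse(tot > 0, 100 * h$kinetic / tot, 0)
  max(ratio)
}
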