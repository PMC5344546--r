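#' Angular section bounds
#'
#' Default analysis sectors of the annulus, as angles (degrees) about the
#' disc center measured counterclockwise from the +x (lateral) axis; the
#' posterior midline is at 270. POST straddles the posterior midline
#' symmetrically; POST-LAT1 and POST-LAT2 are the adjacent 25-degree sectors
#' on the tension side of the lateral bend (the -x side for a bend that
#' lowers +x); ANT straddles the anterior midline.
#'
#' @param post_half_width Half-width of the POST sector (degrees).
#' @param postlat_width Width of each postero-lateral sector (degrees).
#' @param ant_half_width Half-width of the ANT sector (degrees).
#' @param bending_side `"-x"` or `"+x"`: side carrying the postero-lateral
#'   sectors.
#' @return Named list of `c(lo, hi)` angular bounds (degrees in [0, 360)).
#' @export
section_bounds <- function(post_half_width = 20, postlat_width = 25,
                           ant_half_width = 40, bending_side = c("-x", "+x")) {
  bending_side <- match.arg(bending_side)
  post <- c(270 - post_half_width, 270 + post_half_width)
  if (bending_side == "-x") {
    pl1 <- c(270 - post_half_width - postlat_width, 270 - post_half_width)
    pl2 <- c(pl1[1] - postlat_width, pl1[1])
  } else {
    pl1 <- c(270 + post_half_width, 270 + post_half_width + postlat_width)
    pl2 <- c(pl1[2], pl1[2] + postlat_width)
  }
  b <- list(POST = post, `POST-LAT1` = pl1, `POST-LAT2` = pl2,
            ANT = c(90 - ant_half_width, 90 + ant_half_width))
  for (i in seq_along(b)) b[[i]] <- b[[i]] %% 360
  # overlap check on the circle
  segs <- lapply(b, function(x) if (x[1] <= x[2]) list(x) else
    list(c(x[1], 360), c(0, x[2])))
  flat <- do.call(rbind, lapply(unlist(segs, recursive = FALSE), rbind))
  flat <- flat[order(flat[, 1]), , drop = FALSE]
  if (nrow(flat) > 1 && any(flat[-1, 1] < flat[-nrow(flat), 2] - 1e-9))
    stop("configuration error: overlapping angular bounds")
  b
}

in_sector <- function(theta, lo_hi) {
  t <- theta %% 360
  if (lo_hi[1] <= lo_hi[2]) t >= lo_hi[1] & t < lo_hi[2]
  else t >= lo_hi[1] | t < lo_hi[2]
}

#' Map annulus elements to analysis sections and subsections
#'
#' Assigns every AF element a section label (angular sector), an axial band
#' (cranial/middle/caudal third of its column) and a radial band
#' (inner/outer half of the annulus thickness); each section therefore has
#' six subsections.
#'
#' @param mesh A `disc_mesh`.
#' @param bounds Angular bounds from [section_bounds()].
#' @return A `section_map` data.frame (one row per element) with columns
#'   `section`, `axial_band`, `radial_band`, `is_af`.
#' @export
build_section_map <- function(mesh, bounds = section_bounds()) {
  stopifnot(inherits(mesh, "disc_mesh"))
  ne <- nrow(mesh$hexes)
  af <- mesh$region %in% c("AF-anterior", "AF-lateral", "AF-posterior")
  section <- rep("other", ne)
  for (nm in names(bounds)) {
    hit <- af & in_sector(mesh$elem$theta, bounds[[nm]])
    section[hit] <- nm
  }
  zf <- mesh$elem$axial_frac
  axial_band <- rep(NA_character_, ne)
  axial_band[af & zf < 1 / 3] <- "caudal"
  axial_band[af & zf >= 1 / 3 & zf < 2 / 3] <- "middle"
  axial_band[af & zf >= 2 / 3] <- "cranial"
  radial_band <- rep(NA_character_, ne)
  rf <- mesh$elem$radial_frac
  radial_band[af & !is.na(rf) & rf <= 0.5] <- "inner"
  radial_band[af & !is.na(rf) & rf > 0.5] <- "outer"
  structure(data.frame(section = section, axial_band = axial_band,
                       radial_band = radial_band, is_af = af,
                       stringsAsFactors = FALSE),
            class = c("section_map", "data.frame"))
}

# local-frame normal stress components of each element (ne x 3: axial,
# circumferential, radial) from the global 6-component mean Cauchy stress.
local_normal_stresses <- function(state, mesh) {
  s <- state$stress
  full <- function(e) matrix(c(s[e, 1], s[e, 4], s[e, 6],
                               s[e, 4], s[e, 2], s[e, 5],
                               s[e, 6], s[e, 5], s[e, 3]), 3, 3)
  ne <- nrow(s)
  out <- matrix(0, ne, 3, dimnames = list(NULL, c("axial", "circumferential",
                                                  "radial")))
  fr <- mesh$frames
  for (e in seq_len(ne)) {
    sig <- full(e)
    out[e, 1] <- fr$axial[e, ] %*% sig %*% fr$axial[e, ]
    out[e, 2] <- fr$circ[e, ] %*% sig %*% fr$circ[e, ]
    out[e, 3] <- fr$rad[e, ] %*% sig %*% fr$rad[e, ]
  }
  out
}

#' Regional averaged tensile stresses
#'
#' Volume-weighted mean of the tensile (Macaulay-positive) part of the
#' local-frame normal stress components over each (section, subsection) and
#' over the axial/radial marginals. By default the positive part is averaged
#' over the full subsection volume; `positive_only = TRUE` averages only
#' over the elements whose stress is positive.
#'
#' @param state A converged `solution_state`.
#' @param map A [build_section_map()] result.
#' @param mesh The `disc_mesh`.
#' @param positive_only Averaging-domain flag (see above).
#' @return A tidy data.frame (`section`, `subset`, `direction`, `value`,
#'   `volume`); `subset` is `cranial/middle/caudal x inner/outer`, one of the
#'   five marginals, or `all`. Empty subsections yield `NA` with a warning.
#' @export
average_regional_stresses <- function(state, map, mesh, positive_only = FALSE) {
  loc <- local_normal_stresses(state, mesh)
  vol <- mesh$volumes
  rows <- list()
  sections <- setdiff(unique(map$section), "other")
  axials <- c("cranial", "middle", "caudal")
  radials <- c("inner", "outer")
  subsets <- c(as.vector(outer(axials, radials, paste, sep = "-")),
               axials, radials, "all")
  for (sec in sections) {
    insec <- map$section == sec
    for (sub in subsets) {
      if (sub == "all") sel <- insec
      else if (sub %in% axials) sel <- insec & map$axial_band == sub
      else if (sub %in% radials) sel <- insec & map$radial_band == sub
      else {
        parts <- strsplit(sub, "-")[[1]]
        sel <- insec & map$axial_band == parts[1] & map$radial_band == parts[2]
      }
      sel[is.na(sel)] <- FALSE
      for (dir in colnames(loc)) {
        if (!any(sel)) {
          warning("empty subsection: ", sec, " / ", sub)
          val <- NA_real_; v <- 0
        } else {
          sp <- pmax(loc[sel, dir], 0)
          w <- vol[sel]
          if (positive_only) {
            pos <- sp > 0
            val <- if (any(pos)) sum(sp[pos] * w[pos]) / sum(w[pos]) else 0
          } else val <- sum(sp * w) / sum(w)
          v <- sum(w)
        }
        rows[[length(rows) + 1]] <- data.frame(
          section = sec, subset = sub, direction = dir, value = val,
          volume = v, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("regional_stress_table", "data.frame")
  out
}

# reference area of a (possibly warped) quad face, via two triangles
quad_area <- function(p1, p2, p3, p4) {
  tri <- function(a, b, c) {
    v1 <- b - a; v2 <- c - a
    0.5 * sqrt(sum(crossprod3(v1, v2)^2))
  }
  tri(p1, p2, p3) + tri(p1, p3, p4)
}
crossprod3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                               a[3] * b[1] - a[1] * b[3],
                               a[1] * b[2] - a[2] * b[1])

#' Stress at the annulus-endplate interface
#'
#' Per section: the axial components of the internal nodal forces
#' transmitted across the caudal AF-CEP interface (assembled from the
#' elements above the interface plane), summed over the section's interface
#' patch and divided by the patch's current (deformed) cross-sectional area,
#' so a uniform true stress field reproduces itself exactly. Tensile
#' positive.
#'
#' @param state A converged `solution_state`.
#' @param mesh The `disc_mesh`.
#' @param map A [build_section_map()] result.
#' @param materials Region-keyed material list (needed to re-assemble the
#'   upper-body internal forces).
#' @param endplate `"caudal"` (default, as used for the reported EP stress)
#'   or `"cranial"`.
#' @return data.frame with `section` and `interface_stress` (MPa).
#' @export
interface_stress <- function(state, mesh, map, materials,
                             endplate = c("caudal", "cranial")) {
  endplate <- match.arg(endplate)
  if (is.null(mesh$node_sets$af_cep_interface_caudal))
    stop("configuration error: missing AF-CEP interface node set")
  lay <- mesh$layers
  if (endplate == "caudal") {
    iface_layer <- lay$first_core_layer
    above <- mesh$elem$layer >= iface_layer
    face_idx <- 1:4 # bottom face of the first core layer
    sign_ax <- -1   # upward force from above body = compression on the patch
  } else {
    iface_layer <- lay$last_core_layer
    above <- mesh$elem$layer <= iface_layer
    face_idx <- 5:8
    sign_ax <- 1    # body below the plane: upward nodal force = tension
  }

  arrays <- material_arrays(mesh, materials)
  sub <- which(above)
  asm <- cpp_assemble(mesh$nodes, mesh$hexes[sub, , drop = FALSE],
                      arrays$mtype[sub], arrays$mpar[sub, , drop = FALSE],
                      arrays$fib1[sub, , drop = FALSE],
                      arrays$fib2[sub, , drop = FALSE],
                      state$swell[sub], state$u,
                      FALSE, FALSE, 1e-6)
  if (!asm$ok) stop("kinematics error in interface re-assembly")
  fz <- asm$fint[seq(3, length(asm$fint), by = 3)]

  xdef <- mesh$nodes + matrix(state$u, ncol = 3, byrow = TRUE)
  sections <- setdiff(unique(map$section), "other")
  out <- data.frame(section = sections, interface_stress = NA_real_)
  for (k in seq_along(sections)) {
    elems <- which(map$section == sections[k] & mesh$elem$layer == iface_layer)
    if (length(elems) == 0) next
    patch_nodes <- unique(as.integer(mesh$hexes[elems, face_idx]))
    area <- 0
    for (e in elems) {
      nd <- mesh$hexes[e, face_idx]
      area <- area + quad_area(xdef[nd[1], ], xdef[nd[2], ],
                               xdef[nd[3], ], xdef[nd[4], ])
    }
    out$interface_stress[k] <- sign_ax * sum(fz[patch_nodes]) / area
  }
  out
}
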