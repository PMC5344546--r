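#' Disc geometry configuration
#'
#' Parametric description of the disc: gross dimensions, endplate
#' thicknesses, nucleus size/offset, mesh resolution and fiber angles.
#' Defaults reproduce the published ovine lumbar L3-4 dimensions
#' (width 30 mm, depth 22 mm, anterior/posterior annulus heights
#' 4.5/2.5 mm, cartilaginous/bony endplates 0.1/0.5 mm).
#'
#' @param width Lateral extent (mm).
#' @param depth Antero-posterior extent (mm).
#' @param af_height_anterior,af_height_posterior Annulus heights (mm);
#'   posterior must not exceed anterior.
#' @param cep_thickness,bep_thickness Cartilaginous / bony endplate
#'   thicknesses (mm).
#' @param np_area_fraction Fraction of the cross-section occupied by the
#'   nucleus, in (0, 1).
#' @param np_posterior_offset Posterior shift of the nucleus centroid as a
#'   fraction of depth.
#' @param superellipse_exponent Exponent of the cross-section contour
#'   `|x/a|^p + |y/b|^p = 1`.
#' @param fiber_angle Fiber inclination to the circumferential direction
#'   (degrees, in (0, 90)); a scalar or a vector named by AF region.
#' @param resolution List with `n_square` (core block divisions, >= 2),
#'   `n_transition` (>= 1), `n_annulus` (annulus rings, >= 2) and
#'   `n_axial` (core layers, >= 2).
#' @return A `disc_geometry_config` object.
#' @export
disc_geometry_config <- function(width = 30, depth = 22,
                                 af_height_anterior = 4.5,
                                 af_height_posterior = 2.5,
                                 cep_thickness = 0.1, bep_thickness = 0.5,
                                 np_area_fraction = 0.4,
                                 np_posterior_offset = 0.05,
                                 superellipse_exponent = 2.5,
                                 fiber_angle = 30,
                                 resolution = list(n_square = 6,
                                                   n_transition = 2,
                                                   n_annulus = 3,
                                                   n_axial = 4)) {
  lens <- c(width, depth, af_height_anterior, af_height_posterior,
            cep_thickness, bep_thickness)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("configuration error: all lengths must be positive")
  if (af_height_posterior > af_height_anterior)
    stop("configuration error: posterior AF height exceeds anterior")
  if (np_area_fraction <= 0 || np_area_fraction >= 1)
    stop("configuration error: np_area_fraction must be in (0, 1)")
  if (superellipse_exponent < 2)
    stop("configuration error: superellipse exponent must be >= 2")
  r <- resolution
  need <- c("n_square", "n_transition", "n_annulus", "n_axial")
  if (!all(need %in% names(r)))
    stop("configuration error: resolution needs ", paste(need, collapse = ", "))
  if (r$n_square < 2 || r$n_annulus < 2 || r$n_axial < 2 || r$n_transition < 1)
    stop("configuration error: resolution too coarse to honor all layers")
  if (min(af_height_posterior, af_height_anterior) <= 2 * cep_thickness)
    stop("configuration error: AF height does not accommodate the CEP layers")
  structure(list(width = width, depth = depth,
                 af_height_anterior = af_height_anterior,
                 af_height_posterior = af_height_posterior,
                 cep_thickness = cep_thickness, bep_thickness = bep_thickness,
                 np_area_fraction = np_area_fraction,
                 np_posterior_offset = np_posterior_offset,
                 superellipse_exponent = superellipse_exponent,
                 fiber_angle = fiber_angle, resolution = r),
            class = "disc_geometry_config")
}

# Point on the superellipse |x/a|^p + |y/b|^p = 1 at parameter angle theta.
superellipse_point <- function(theta, a, b, p) {
  ct <- cos(theta); st <- sin(theta)
  cbind(a * sign(ct) * abs(ct)^(2 / p), b * sign(st) * abs(st)^(2 / p))
}

#' Build the parametric disc mesh
#'
#' Generates a structured hexahedral ("butterfly") mesh: a central block and
#' transition rings fill the nucleus, annulus rings fill the AF, and the
#' column heights interpolate linearly from the posterior to the anterior
#' annulus height. Thin cartilaginous endplate layers cap the nucleus and
#' inner annulus; bony endplate layers cap the whole disc. Local frames and
#' fiber fields are attached via [compute_local_frames()] and
#' [assign_fiber_field()].
#'
#' @param config A [disc_geometry_config()].
#' @return A `disc_mesh` object: node coordinates (mm), 8-node hex
#'   connectivity, region labels, per-element metadata, node sets, local
#'   frames and fiber directions.
#' @export
build_disc_mesh <- function(config = disc_geometry_config()) {
  stopifnot(inherits(config, "disc_geometry_config"))
  r <- config$resolution
  ns <- r$n_square; nt <- r$n_transition; nr <- r$n_annulus; nz <- r$n_axial
  nbep <- max(1L, as.integer(round(nz / 4)))
  ncep <- max(1L, as.integer(round(nz / 4)))
  a <- config$width / 2; b <- config$depth / 2
  p <- config$superellipse_exponent
  snp <- sqrt(config$np_area_fraction)
  cnp <- c(0, -config$np_posterior_offset * config$depth)

  nspoke <- 4 * ns
  dth <- pi / 2 / ns
  th <- pi / 4 + (0:(nspoke - 1)) * dth

  pout <- superellipse_point(th, a, b, p)
  pnp <- sweep(snp * pout, 2, cnp, "+")

  ## --- 2D nodes ------------------------------------------------------------
  # core block boundary: half-scale copy of the NP polygon (same spokes), so
  # transition rings interpolate along radial spokes; interior via Coons patch
  pblk <- sweep(0.5 * (pnp - matrix(cnp, nspoke, 2, byrow = TRUE)),
                2, cnp, "+")
  blk_of_spoke <- function(s) pblk[(s %% nspoke) + 1, ] # s is 0-based
  # boundary curves of the core grid in (i, j) parameter space
  bot <- t(vapply(0:ns, function(i) blk_of_spoke(2 * ns + i), c(0, 0)))
  rgt <- t(vapply(0:ns, function(j) blk_of_spoke(3 * ns + j), c(0, 0)))
  top <- t(vapply(0:ns, function(i) blk_of_spoke(ns - i), c(0, 0)))
  lft <- t(vapply(0:ns, function(j) blk_of_spoke(2 * ns - j), c(0, 0)))
  core_id <- matrix(0L, ns + 1, ns + 1)
  xy <- matrix(0, 0, 2)
  for (j in 0:ns) for (i in 0:ns) {
    u <- i / ns; v <- j / ns
    pt <- (1 - v) * bot[i + 1, ] + v * top[i + 1, ] +
      (1 - u) * lft[j + 1, ] + u * rgt[j + 1, ] -
      ((1 - u) * (1 - v) * bot[1, ] + u * (1 - v) * bot[ns + 1, ] +
         u * v * top[ns + 1, ] + (1 - u) * v * top[1, ])
    xy <- rbind(xy, pt)
    core_id[i + 1, j + 1] <- nrow(xy)
  }
  # block boundary node id for spoke s (0-based), matching theta = 45 + 90*s/ns
  block_node <- integer(nspoke)
  for (s in 0:(nspoke - 1)) {
    if (s <= ns) { i <- ns - s; j <- ns
    } else if (s <= 2 * ns) { i <- 0; j <- 2 * ns - s
    } else if (s <= 3 * ns) { i <- s - 2 * ns; j <- 0
    } else { i <- ns; j <- s - 3 * ns }
    block_node[s + 1] <- core_id[i + 1, j + 1]
  }
  nring <- nt + nr
  ring_id <- matrix(0L, nspoke, nring)
  for (q in 1:nring) for (s in 1:nspoke) {
    if (q <= nt) {
      t <- q / nt
      pt <- (1 - t) * xy[block_node[s], ] + t * pnp[s, ]
    } else {
      t <- (q - nt) / nr
      pt <- (1 - t) * pnp[s, ] + t * pout[s, ]
    }
    xy <- rbind(xy, pt)
    ring_id[s, q] <- nrow(xy)
  }
  n2d <- nrow(xy)

  ## --- 2D cells ------------------------------------------------------------
  quads <- matrix(0L, 0, 4)
  qtype <- character(0)   # "NP" or "AF"
  qring <- numeric(0)     # AF radial fraction (NA for NP)
  for (j in 1:ns) for (i in 1:ns) {
    quads <- rbind(quads, c(core_id[i, j], core_id[i + 1, j],
                            core_id[i + 1, j + 1], core_id[i, j + 1]))
    qtype <- c(qtype, "NP"); qring <- c(qring, NA)
  }
  ringn <- function(s, q) if (q == 0) block_node[s] else ring_id[s, q]
  for (q in 1:nring) for (s in 1:nspoke) {
    s2 <- if (s == nspoke) 1L else s + 1L
    quads <- rbind(quads, c(ringn(s, q - 1), ringn(s, q),
                            ringn(s2, q), ringn(s2, q - 1)))
    if (q <= nt) { qtype <- c(qtype, "NP"); qring <- c(qring, NA) }
    else { qtype <- c(qtype, "AF"); qring <- c(qring, (q - nt - 0.5) / nr) }
  }
  nq <- nrow(quads)
  qcent <- cbind(rowMeans(matrix(xy[quads, 1], nq, 4)),
                 rowMeans(matrix(xy[quads, 2], nq, 4)))
  qtheta <- atan2(qcent[, 2], qcent[, 1]) * 180 / pi  # deg, 0 = +x lateral

  ## --- axial levels per 2D node ---------------------------------------------
  hfun <- function(y) {
    config$af_height_posterior +
      (y + b) / (2 * b) * (config$af_height_anterior - config$af_height_posterior)
  }
  H <- hfun(xy[, 2])
  cep <- config$cep_thickness; bep <- config$bep_thickness
  nlay <- nz + 2 * ncep + 2 * nbep
  nlev <- nlay + 1
  zlev <- matrix(0, n2d, nlev)
  for (k in 1:n2d) {
    h <- H[k]
    z <- c(seq(-h / 2 - bep, -h / 2, length.out = nbep + 1),
           seq(-h / 2, -h / 2 + cep, length.out = ncep + 1)[-1],
           seq(-h / 2 + cep, h / 2 - cep, length.out = nz + 1)[-1],
           seq(h / 2 - cep, h / 2, length.out = ncep + 1)[-1],
           seq(h / 2, h / 2 + bep, length.out = nbep + 1)[-1])
    zlev[k, ] <- z
  }

  nodes <- matrix(0, n2d * nlev, 3)
  for (lv in 1:nlev) {
    idx <- (lv - 1) * n2d + seq_len(n2d)
    nodes[idx, 1:2] <- xy
    nodes[idx, 3] <- zlev[, lv]
  }

  ## --- elements --------------------------------------------------------------
  layer_kind <- c(rep("BEP-caudal", nbep), rep("CEPlayer-caudal", ncep),
                  rep("core", nz), rep("CEPlayer-cranial", ncep),
                  rep("BEP-cranial", nbep))
  ne <- nq * nlay
  hexes <- matrix(0L, ne, 8)
  region <- character(ne)
  e_theta <- numeric(ne); e_rfrac <- rep(NA_real_, ne)
  e_layer <- integer(ne); e_quad <- integer(ne)
  af_region_of <- function(theta) {
    if (abs(((theta - 90) + 180) %% 360 - 180) <= 50) "AF-anterior"
    else if (abs(((theta + 90) + 180) %% 360 - 180) <= 50) "AF-posterior"
    else "AF-lateral"
  }
  e <- 0L
  for (lv in 1:nlay) {
    off0 <- (lv - 1) * n2d; off1 <- lv * n2d
    for (qd in 1:nq) {
      e <- e + 1L
      hexes[e, ] <- c(quads[qd, ] + off0, quads[qd, ] + off1)
      e_theta[e] <- qtheta[qd]; e_layer[e] <- lv; e_quad[e] <- qd
      kind <- layer_kind[lv]
      if (kind %in% c("BEP-caudal", "BEP-cranial")) {
        region[e] <- kind
      } else if (kind == "core") {
        if (qtype[qd] == "NP") region[e] <- "NP"
        else { region[e] <- af_region_of(qtheta[qd]); e_rfrac[e] <- qring[qd] }
      } else { # CEP-position layer: CEP over NP and inner AF, AF over outer AF
        inner <- qtype[qd] == "NP" || (!is.na(qring[qd]) && qring[qd] <= 0.5)
        if (inner) {
          region[e] <- if (kind == "CEPlayer-caudal") "CEP-caudal" else "CEP-cranial"
        } else {
          region[e] <- af_region_of(qtheta[qd]); e_rfrac[e] <- qring[qd]
        }
      }
    }
  }

  ## axial fraction of AF/core elements within their column's disc span
  e_zfrac <- rep(NA_real_, ne)
  zc <- (nodes[hexes[, 1], 3] + nodes[hexes[, 7], 3]) / 2
  for (qd in 1:nq) {
    idx <- which(e_quad == qd & region %in%
                   c("NP", "AF-anterior", "AF-lateral", "AF-posterior"))
    if (length(idx) == 0) next
    zr <- range(c(nodes[hexes[idx, 1:4], 3], nodes[hexes[idx, 5:8], 3]))
    e_zfrac[idx] <- (zc[idx] - zr[1]) / (zr[2] - zr[1])
  }

  ## node sets
  lvl_of <- function(lv) (lv - 1) * n2d + seq_len(n2d)
  core_bot_lv <- nbep + ncep + 1
  core_top_lv <- nbep + ncep + nz + 1
  af_quads <- which(qtype == "AF")
  af_nodes2d <- sort(unique(as.integer(quads[af_quads, ])))
  node_sets <- list(
    caudal_fixed = lvl_of(1),
    cranial_coupled = lvl_of(nlev),
    af_cep_interface_caudal = (core_bot_lv - 1) * n2d + af_nodes2d,
    af_cep_interface_cranial = (core_top_lv - 1) * n2d + af_nodes2d
  )

  mesh <- structure(list(
    nodes = nodes, hexes = hexes, region = region,
    elem = data.frame(theta = e_theta, radial_frac = e_rfrac,
                      axial_frac = e_zfrac, layer = e_layer, quad2d = e_quad),
    node_sets = node_sets, config = config,
    n2d = n2d, nlev = nlev,
    layers = list(n_bep = nbep, n_cep = ncep, n_axial = nz,
                  core_bottom_level = core_bot_lv,
                  core_top_level = core_top_lv,
                  first_core_layer = nbep + ncep + 1L,
                  last_core_layer = nbep + ncep + nz)
  ), class = "disc_mesh")
  mesh$volumes <- cpp_elem_volumes(mesh$nodes, mesh$hexes)
  mesh <- compute_local_frames(mesh)
  assign_fiber_field(mesh, config$fiber_angle)
}

#' Per-element local circumferential / radial / axial frames
#'
#' The radial direction is the in-plane outward normal of the superellipse
#' level curve through the element centroid, the axial direction is the
#' global spine axis, and the circumferential direction completes the
#' right-handed triad. An element centroid at the contour center (undefined
#' tangent) falls back to the global x axis with a warning.
#'
#' @param mesh A `disc_mesh`.
#' @return The mesh with a `frames` field (list of matrices `circ`, `rad`,
#'   `axial`, one row per element).
#' @export
compute_local_frames <- function(mesh) {
  stopifnot(inherits(mesh, "disc_mesh"))
  cfg <- mesh$config
  a <- cfg$width / 2; b <- cfg$depth / 2; p <- cfg$superellipse_exponent
  ne <- nrow(mesh$hexes)
  cent <- elem_centroids(mesh)
  gx <- (p / a) * abs(cent[, 1] / a)^(p - 1) * sign(cent[, 1])
  gy <- (p / b) * abs(cent[, 2] / b)^(p - 1) * sign(cent[, 2])
  nrm <- sqrt(gx^2 + gy^2)
  deg <- nrm < 1e-12
  if (any(deg)) {
    warning(sum(deg), " element centroid(s) at the contour center; ",
            "radial direction falls back to global x")
    gx[deg] <- 1; gy[deg] <- 0; nrm[deg] <- 1
  }
  rad <- cbind(gx / nrm, gy / nrm, 0)
  axial <- matrix(rep(c(0, 0, 1), each = ne), ne, 3)
  # circ = rad x axial (right-handed triad circ, rad, axial)
  circ <- cbind(rad[, 2], -rad[, 1], 0)
  mesh$frames <- list(circ = circ, rad = rad, axial = axial)
  mesh
}

#' Assign the two-family fiber field to the annulus
#'
#' Each AF element receives two unit fiber vectors at `+angle` and `-angle`
#' to its local circumferential direction, lying in the circumferential-axial
#' plane (mirror images across the circumferential axis).
#'
#' @param mesh A `disc_mesh` with local frames.
#' @param fiber_angle Degrees in (0, 90); scalar or named by AF region.
#' @return The mesh with `fiber1`/`fiber2` matrices (NA rows outside the AF).
#' @export
assign_fiber_field <- function(mesh, fiber_angle = 30) {
  stopifnot(inherits(mesh, "disc_mesh"), !is.null(mesh$frames))
  af_regions <- c("AF-anterior", "AF-lateral", "AF-posterior")
  if (length(fiber_angle) == 1 && is.null(names(fiber_angle))) {
    ang <- stats::setNames(rep(fiber_angle, 3), af_regions)
  } else {
    ang <- fiber_angle
    if (!all(af_regions %in% names(ang)))
      stop("configuration error: fiber_angle must name all AF regions")
  }
  if (any(ang <= 0 | ang >= 90))
    stop("configuration error: fiber angle must be in (0, 90) degrees")
  ne <- nrow(mesh$hexes)
  f1 <- matrix(NA_real_, ne, 3); f2 <- matrix(NA_real_, ne, 3)
  for (rg in af_regions) {
    idx <- which(mesh$region == rg)
    if (length(idx) == 0) next
    al <- ang[[rg]] * pi / 180
    f1[idx, ] <- cos(al) * mesh$frames$circ[idx, ] +
      sin(al) * mesh$frames$axial[idx, ]
    f2[idx, ] <- cos(al) * mesh$frames$circ[idx, ] -
      sin(al) * mesh$frames$axial[idx, ]
  }
  mesh$fiber1 <- f1; mesh$fiber2 <- f2
  mesh$fiber_angle <- ang
  mesh
}

#' Element centroids
#' @param mesh A `disc_mesh` (or any mesh list with `nodes` and `hexes`).
#' @return Matrix `ne x 3` of centroid coordinates.
#' @export
elem_centroids <- function(mesh) {
  ne <- nrow(mesh$hexes)
  cbind(rowMeans(matrix(mesh$nodes[mesh$hexes, 1], ne, 8)),
        rowMeans(matrix(mesh$nodes[mesh$hexes, 2], ne, 8)),
        rowMeans(matrix(mesh$nodes[mesh$hexes, 3], ne, 8)))
}

#' Minimum scaled Jacobian per element
#'
#' Brute-force scan of the reference Jacobian at all Gauss points of every
#' hexahedron, normalised by the element volume; positive values certify a
#' valid (non-inverted) reference mesh.
#'
#' @param mesh A mesh with `nodes` and `hexes`.
#' @return Numeric vector, one value per element.
#' @export
scaled_jacobians <- function(mesh) {
  cpp_scaled_jacobians(mesh$nodes, mesh$hexes)
}
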