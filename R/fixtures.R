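#' Verification fixture meshes
#'
#' Deterministic small meshes used by the solver and post-processing tests:
#' \describe{
#'   \item{single-element}{one unit-cube hexahedron.}
#'   \item{patch-block}{3x3x3 unit cube with deterministically perturbed
#'     interior nodes (classic patch-test configuration).}
#'   \item{tension-bar}{1x1x10 mm bar of 10 elements along z, equipped with
#'     the layer/interface metadata needed by [interface_stress()].}
#'   \item{mini-disc}{a ~500-element disc at default dimensions.}
#' }
#'
#' Box fixtures carry a single region label `"block"`; pass a materials list
#' keyed by `"block"` when solving on them.
#'
#' @param name Fixture name.
#' @return A mesh list (for `mini-disc`, a full `disc_mesh`).
#' @export
make_fixture <- function(name = c("single-element", "patch-block",
                                  "tension-bar", "mini-disc")) {
  name <- match.arg(name)
  if (name == "mini-disc") {
    return(build_disc_mesh(disc_geometry_config(
      resolution = list(n_square = 4, n_transition = 2, n_annulus = 2,
                        n_axial = 2))))
  }
  box_mesh <- function(nx, ny, nz, lx, ly, lz, jitter = 0) {
    xs <- seq(0, lx, length.out = nx + 1)
    ys <- seq(0, ly, length.out = ny + 1)
    zs <- seq(0, lz, length.out = nz + 1)
    nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    dimnames(nodes) <- NULL
    nid <- function(i, j, k) i + (nx + 1) * (j - 1) + (nx + 1) * (ny + 1) * (k - 1)
    if (jitter > 0) {
      h <- c(lx / nx, ly / ny, lz / nz)
      for (k in 2:nz) for (j in 2:ny) for (i in 2:nx) {
        n <- nid(i, j, k)
        # deterministic pseudo-random interior perturbation
        ph <- sin(13.7 * i + 7.3 * j + 3.1 * k) * c(1, -0.7, 0.4)
        nodes[n, ] <- nodes[n, ] + jitter * h * ph
      }
    }
    hexes <- matrix(0L, nx * ny * nz, 8)
    e <- 0
    for (k in 1:nz) for (j in 1:ny) for (i in 1:nx) {
      e <- e + 1
      hexes[e, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                      nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                      nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
    }
    m <- list(nodes = nodes, hexes = hexes,
              region = rep("block", nrow(hexes)),
              elem = data.frame(layer = rep(1:nz, each = nx * ny)),
              node_sets = list(), dims = c(nx, ny, nz))
    m$volumes <- cpp_elem_volumes(m$nodes, m$hexes)
    m
  }
  switch(name,
    "single-element" = {
      m <- box_mesh(1, 1, 1, 1, 1, 1)
      m$node_sets <- list(caudal_fixed = 1:4, cranial_coupled = 5:8)
      m
    },
    "patch-block" = box_mesh(3, 3, 3, 1, 1, 1, jitter = 0.15),
    "tension-bar" = {
      m <- box_mesh(1, 1, 10, 1, 1, 10)
      m$layers <- list(first_core_layer = 2L, last_core_layer = 9L)
      n2d <- 4
      m$node_sets <- list(
        caudal_fixed = 1:4,
        cranial_coupled = 40 + (1:4),
        af_cep_interface_caudal = n2d * 1 + (1:4)
      )
      m
    })
}
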