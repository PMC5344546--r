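# Section mapping, regional tensile-stress averaging, interface stress.

mesh <- build_disc_mesh()
map <- build_section_map(mesh)

fake_state <- function(stress6, ne = nrow(mesh$hexes)) {
  structure(list(stress = matrix(stress6, ne, 6, byrow = TRUE),
                 u = numeric(3 * nrow(mesh$nodes)),
                 swell = rep(1, ne)), class = "solution_state")
}

test_that("section map: POST straddles the posterior midline; six subsections", {
  af <- map$is_af
  expect_true(all(map$section[!af] == "other"))
  post <- which(map$section == "POST")
  expect_gt(length(post), 0)
  cent <- elem_centroids(mesh)
  vl <- sum(mesh$volumes[post][cent[post, 1] < 0])
  vr <- sum(mesh$volumes[post][cent[post, 1] > 0])
  expect_equal(vl, vr, tolerance = 0.01)
  subs <- table(paste(map$axial_band[post], map$radial_band[post]))
  expect_equal(length(subs), 6)
  expect_error(section_bounds(post_half_width = 80, postlat_width = 40),
               "overlap")
})

test_that("postero-lateral sectors mirror across the posterior midline", {
  m1 <- build_section_map(mesh, section_bounds(bending_side = "-x"))
  m2 <- build_section_map(mesh, section_bounds(bending_side = "+x"))
  v1 <- sum(mesh$volumes[m1$section == "POST-LAT1"])
  v2 <- sum(mesh$volumes[m2$section == "POST-LAT1"])
  expect_equal(v1, v2, tolerance = 0.01)
})

test_that("uniform uniaxial field averages to itself in the axial direction only", {
  st <- fake_state(c(0, 0, 5, 0, 0, 0)) # sigma_zz = 5 everywhere
  tab <- average_regional_stresses(st, map, mesh)
  expect_equal(tab$value[tab$direction == "axial"],
               rep(5, sum(tab$direction == "axial")))
  expect_equal(tab$value[tab$direction != "axial"],
               rep(0, sum(tab$direction != "axial")))
})

test_that("tensile averaging convention: positive part over the full volume", {
  # +4 / -4 axial split over the POST section; expected value computed by an
  # independent hand formula from the element volumes
  st <- fake_state(c(0, 0, 0, 0, 0, 0))
  post <- which(map$section == "POST")
  pos_set <- post[seq(1, length(post), by = 2)]
  neg_set <- setdiff(post, pos_set)
  st$stress[pos_set, 3] <- 4
  st$stress[neg_set, 3] <- -4
  tab <- average_regional_stresses(st, map, mesh)
  got <- tab$value[tab$section == "POST" & tab$subset == "all" &
                     tab$direction == "axial"]
  expected <- 4 * sum(mesh$volumes[pos_set]) / sum(mesh$volumes[post])
  expect_equal(got, expected, tolerance = 1e-12)
  # the alternative averaging domain (positive elements only) gives 4
  tab2 <- average_regional_stresses(st, map, mesh, positive_only = TRUE)
  got2 <- tab2$value[tab2$section == "POST" & tab2$subset == "all" &
                       tab2$direction == "axial"]
  expect_equal(got2, 4, tolerance = 1e-12)
})

test_that("partition consistency: section mean equals volume-weighted subsection mean", {
  set.seed(123)
  st <- fake_state(c(0, 0, 0, 0, 0, 0))
  st$stress <- matrix(rnorm(nrow(mesh$hexes) * 6, 0, 2), ncol = 6)
  tab <- average_regional_stresses(st, map, mesh)
  for (sec in c("POST", "POST-LAT1", "ANT")) {
    for (dir in c("axial", "circumferential", "radial")) {
      sub <- tab[tab$section == sec & tab$direction == dir &
                   grepl("-", tab$subset), ]
      allv <- tab$value[tab$section == sec & tab$direction == dir &
                          tab$subset == "all"]
      expect_equal(sum(sub$value * sub$volume) / sum(sub$volume), allv,
                   tolerance = 1e-10)
    }
  }
})

test_that("regional table is invariant under rigid rotation (frames co-rotate)", {
  set.seed(7)
  st <- fake_state(c(0, 0, 0, 0, 0, 0))
  st$stress <- matrix(rnorm(nrow(mesh$hexes) * 6, 0, 1), ncol = 6)
  tab <- average_regional_stresses(st, map, mesh)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  m2 <- mesh
  m2$nodes <- mesh$nodes %*% t(R)
  for (f in names(m2$frames)) m2$frames[[f]] <- m2$frames[[f]] %*% t(R)
  st2 <- st
  for (e in seq_len(nrow(st$stress))) {
    s <- sym6_to_full(st$stress[e, ])
    sr <- R %*% s %*% t(R)
    st2$stress[e, ] <- c(sr[1, 1], sr[2, 2], sr[3, 3], sr[1, 2], sr[2, 3],
                         sr[1, 3])
  }
  tab2 <- average_regional_stresses(st2, map, m2)
  expect_equal(tab2$value, tab$value, tolerance = 1e-10)
})

test_that("empty subsections are flagged with a warning, not a crash", {
  # force an empty cranial band in one section
  map2 <- map
  idx <- map2$section == "POST" & map2$axial_band == "cranial"
  map2$axial_band[which(idx)] <- "middle"
  st <- fake_state(c(0, 0, 1, 0, 0, 0))
  expect_warning(tab <- average_regional_stresses(st, map2, mesh), "empty")
  expect_true(anyNA(tab$value))
})

test_that("interface stress equals the uniform stress on a tension bar", {
  bar <- make_fixture("tension-bar")
  mats <- block_mats(linear_elastic_params(24, 0.4))
  bot <- bar$node_sets$caudal_fixed
  top <- bar$node_sets$cranial_coupled
  # stress-free lateral faces: prescribe only axial motion + rigid-body pins
  presc <- rbind(
    data.frame(node = bot, dof = 3, value = 0),
    data.frame(node = top, dof = 3, value = 0.05),
    data.frame(node = 1, dof = 1, value = 0),
    data.frame(node = 1, dof = 2, value = 0),
    data.frame(node = 2, dof = 2, value = 0))
  st <- solve_quasi_static(bar, mats, boundary = list(prescribed = presc),
                           cfg = solver_config(increments = 2, tol = 1e-10))
  sig <- st$stress[5, 3] # mid-bar axial stress (uniform field)
  expect_equal(diff(range(st$stress[, 3])), 0, tolerance = 1e-8)
  bmap <- data.frame(section = rep("BAR", nrow(bar$hexes)))
  ifc <- interface_stress(st, bar, bmap, mats)
  expect_equal(ifc$interface_stress, sig, tolerance = 1e-8)
  # zero-load state gives zero interface stress
  st0 <- st; st0$u <- numeric(length(st$u))
  ifc0 <- interface_stress(st0, bar, bmap, mats)
  expect_equal(ifc0$interface_stress, 0, tolerance = 1e-12)
  # missing interface set is a configuration error
  bar2 <- bar; bar2$node_sets$af_cep_interface_caudal <- NULL
  expect_error(interface_stress(st, bar2, bmap, mats), "configuration")
})
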