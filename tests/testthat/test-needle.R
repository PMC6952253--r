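test_that("nearest_nodes agrees with the brute-force point-segment oracle", {
  set.seed(21)
  pos <- matrix(runif(1500, -40, 40), 500, 3)
  nd <- needle_state(c(35, 0, 0), c(-1, 0, 0), length = 100)
  expect_equal(nrow(nearest_nodes(pos + 500, nd, 2)), 0L)

  for (i in 1:10) {
    tip <- runif(3, -30, 30)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    nd <- needle_state(tip, dir, length = 80)
    got <- nearest_nodes(pos, nd, 3)
    d <- brute_segment_distances(pos, tip, dir, 80)
    expect_identical(got$node, which(d <= 3))
    expect_equal(got$distance, d[d <= 3], tolerance = 1e-12)
    expect_true(all(got$axial >= 0 & got$axial <= 80))
  }

  # node exactly on the axis interior
  nd <- needle_state(c(10, 0, 0), c(1, 0, 0), length = 20)
  got <- nearest_nodes(rbind(c(0, 0, 0)), nd, 1)
  expect_equal(got$distance, 0)
  expect_equal(got$axial, 10)
})

test_that("coupling forces obey Hooke's law and action-reaction", {
  me <- small_ellipsoid_mesh()
  mod <- build_fem_model(me)
  st <- fem_state(mod)

  # needle through the mesh centre along +x
  nd <- needle_state(c(30, 0, 0), c(1, 0, 0), length = 80, phase = "inserted")
  cp <- coupling_params()
  res <- coupling_forces(mod, st, nd, cp)
  expect_gt(length(res$coupled_nodes), 0L)
  # lateral node forces are perpendicular to the needle direction
  expect_lt(max(abs(res$node_forces[, 1])), 1e-12)
  # action-reaction: tissue total + needle reaction = 0
  expect_lt(max(abs(colSums(res$node_forces) + res$needle_force)), 1e-12)

  # single coupled node at a 1 mm offset: pure Hooke's law
  m1 <- unit_tet_mesh()
  mod1 <- build_fem_model(m1)
  # axis along x at (y, z) = (0, 2): only node (0,0,1) is within 1.05 mm
  nd1 <- needle_state(c(5, 0, 2), c(1, 0, 0), length = 20, phase = "inserted")
  cp1 <- coupling_params(d_thr = 1.05, k_perp = 0.5, mu_viscous = 0,
                         f_coulomb_per_node = 0)
  res1 <- coupling_forces(mod1, fem_state(mod1), nd1, cp1)
  expect_identical(res1$coupled_nodes, 4L)
  expect_equal(res1$node_forces[1, ], c(0, 0, 0.5), tolerance = 1e-12)
  expect_equal(res1$needle_force, -res1$node_forces[1, ], tolerance = 1e-12)

  # on-axis nodes with zero relative velocity produce no force
  nd0 <- needle_state(c(0, 0, 0) + c(5, 0, 0), c(1, 0, 0), length = 20,
                      phase = "inserted")
  res0 <- coupling_forces(mod1, fem_state(mod1), nd0,
                          coupling_params(d_thr = 1e-6))
  expect_equal(res0$needle_force, c(0, 0, 0))

  expect_error(coupling_forces(mod1, fem_state(mod1),
                               needle_state(c(0, 0, 0), c(1, 0, 0)), cp),
               "inserted")
})

test_that("needle force magnitude grows with stiffness and lateral offset", {
  m1 <- unit_tet_mesh()
  mod1 <- build_fem_model(m1)
  mk <- function(k_perp, offset) {
    nd <- needle_state(c(0, offset, 0.5), c(0, 0, -1), length = 10,
                       phase = "inserted")
    cp <- coupling_params(d_thr = 20, k_perp = k_perp, mu_viscous = 0,
                          f_coulomb_per_node = 0)
    sqrt(sum(coupling_forces(mod1, fem_state(mod1), nd, cp)$needle_force^2))
  }
  f_by_k <- vapply(c(0.1, 0.3, 0.6, 1.2), mk, 1, offset = 2)
  expect_true(all(diff(f_by_k) > 0))
  f_by_off <- vapply(c(1.5, 2, 3, 4), function(o) mk(0.3, o), 1)
  expect_true(all(diff(f_by_off) >= 0))
})

test_that("surface gap is signed along the needle direction", {
  me <- small_ellipsoid_mesh()  # semi-axes 20, 12, 12 at the origin
  nd_out <- needle_state(c(30, 0, 0), c(-1, 0, 0))
  g <- surface_gap(me, nd_out)
  expect_equal(g, 10, tolerance = 0.5)  # surface near x = 20

  nd_in <- needle_state(c(15, 0, 0), c(-1, 0, 0))
  gi <- surface_gap(me, nd_in)
  expect_lt(gi, 0)
  expect_equal(gi, -5, tolerance = 0.5)

  nd_miss <- needle_state(c(0, 200, 0), c(0, 0, 1))
  expect_identical(surface_gap(me, nd_miss), Inf)
})

test_that("puncture state machine follows the membrane ramp closed form", {
  cp <- coupling_params(f_puncture = 1.5, k_membrane = 0.5, drop_factor = 0.3)
  speed <- 5; dt <- 1e-3
  nd <- needle_state(c(10, 0, 0), c(-1, 0, 0))
  gap0 <- 4
  depth_at_puncture <- NA
  forces <- numeric(0)
  for (k in 0:2000) {
    gap <- gap0 - speed * k * dt
    was <- nd$phase
    nd <- puncture_update(nd, gap, params = cp)
    forces <- c(forces, nd$membrane_force)
    if (was != "inserted" && nd$phase == "inserted") {
      depth_at_puncture <- -gap
      break
    }
  }
  # transition at penetration depth f_puncture / k_membrane (+- one step)
  expect_equal(depth_at_puncture, cp$f_puncture / cp$k_membrane,
               tolerance = speed * dt / (cp$f_puncture / cp$k_membrane))
  # force drop of (1 - drop_factor) f_puncture across the transition
  n <- length(forces)
  drop <- forces[n - 1] - forces[n]
  expect_equal(drop, (1 - cp$drop_factor) * cp$f_puncture,
               tolerance = cp$k_membrane * speed * dt * 2)

  # free needle above the surface stays free with zero membrane force
  ndf <- puncture_update(needle_state(c(10, 0, 0), c(-1, 0, 0)), 2, params = cp)
  expect_identical(ndf$phase, "free")
  expect_identical(ndf$membrane_force, 0)

  # retraction from inserted releases the needle
  ndr <- needle_state(c(10, 0, 0), c(-1, 0, 0), phase = "inserted")
  ndr <- puncture_update(ndr, 1, params = cp)
  expect_identical(ndr$phase, "free")
})

test_that("haptic force composes coupling reaction and membrane resistance", {
  nd <- needle_state(c(0, 0, 0), c(0, 0, 1), phase = "at_surface",
                     membrane_force = 0.3)
  f <- haptic_force(NULL, nd)
  expect_equal(f, c(0, 0, -0.3))

  coup <- structure(list(needle_force = c(0.1, -0.2, 0.05)),
                    class = "coupling_result")
  expect_equal(haptic_force(coup, nd), c(0.1, -0.2, 0.05 - 0.3))

  ndf <- needle_state(c(0, 0, 0), c(0, 0, 1))
  expect_equal(haptic_force(NULL, ndf), c(0, 0, 0))
  expect_error(haptic_force(coup, nd, membrane_force = NaN), "non-finite")
})
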