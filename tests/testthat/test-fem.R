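test_that("element stiffness is symmetric PSD with six rigid modes; mass is conserved", {
  mod <- build_fem_model(unit_tet_mesh())
  K <- mod$element_stiffness[, , 1]
  expect_lt(max(abs(K - t(K))), 1e-8 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(ev)))
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)  # rigid-body nullspace

  me <- small_ellipsoid_mesh()
  mode <- build_fem_model(me)
  expect_equal(sum(mode$lumped_mass),
               mode$material$rho * sum(tet_volumes(me)) * 1e-9,
               tolerance = 1e-9)
})

test_that("invalid material and meshes are rejected at model build", {
  expect_error(material_params(nu = 0.5), "nu")
  expect_error(material_params(E = -1), "E")
  m <- unit_tet_mesh(pelvis = integer(0))
  expect_error(build_fem_model(m, constrained = integer(0)), "non-empty")
})

test_that("polar rotation extraction matches the SVD oracle", {
  expect_equal(element_rotation(diag(3)), diag(3))

  R30 <- rot_about(c(0, 0, 1), pi / 6)
  expect_equal(element_rotation(R30), R30, tolerance = 1e-10)

  set.seed(7)
  for (i in 1:20) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.3), 3, 3)
    if (det(F) <= 0.05) next
    sv <- svd(F)  # independent oracle: closest rotation
    Ro <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
    expect_equal(element_rotation(F), Ro, tolerance = 1e-8)
  }
  expect_error(element_rotation(-diag(3)), "inverted")
})

test_that("internal forces vanish at rest and under rigid motions", {
  me <- small_ellipsoid_mesh()
  mod <- build_fem_model(me)
  st <- fem_state(mod)
  expect_true(all(internal_forces(mod, st) == 0))

  # frame indifference: rigid rotation + translation of the rest shape
  Q <- rot_about(c(1, 2, 0.5), 0.8)
  u <- sweep(me$nodes %*% t(Q), 2, c(5, -3, 2), "+") - me$nodes
  st2 <- structure(list(u = u, v = 0 * u, t = 0), class = "fem_state")
  f <- internal_forces(mod, st2)
  h <- mean((tet_volumes(me) * 12)^(1 / 3))  # typical element length, mm
  expect_lt(max(abs(f)), 1e-6 * (mod$material$E / 1e6) * h)
})

test_that("corotational forces match a dense linear-elastic oracle at small strain", {
  m <- unit_tet_mesh()
  mod <- build_fem_model(m)
  u <- matrix(0, 4, 3); u[4, 3] <- 0.01
  f <- internal_forces(mod, fem_state(mod, u = u))
  Kd <- dense_linear_stiffness(m)
  f_lin <- -matrix(Kd %*% as.vector(t(u)), 4, 3, byrow = TRUE)
  expect_equal(f[4, ], f_lin[4, ], tolerance = 1e-6)

  # Newton's third law on a free mesh
  me <- small_ellipsoid_mesh()
  mode <- build_fem_model(me)
  set.seed(11)
  up <- matrix(rnorm(3 * nrow(me$nodes), sd = 0.02), ncol = 3)
  fe <- internal_forces(mode, structure(list(u = up, v = 0 * up, t = 0),
                                        class = "fem_state"))
  expect_lt(max(abs(colSums(fe))), 1e-9 * max(abs(fe)))
})

test_that("a constant-strain patch reproduces uniaxial stress sigma = E eps", {
  eps <- 1e-3; nu <- 0.3
  L <- c(10, 8, 6)
  m <- tet_mesh_block(L, c(4L, 3L, 3L))
  m$node_sets$pelvis <- which(abs(m$nodes[, 1]) < 1e-9)
  mod <- build_fem_model(m)
  # uniaxial-stress displacement field with free lateral contraction
  u <- cbind(eps * m$nodes[, 1], -nu * eps * m$nodes[, 2],
             -nu * eps * m$nodes[, 3])
  f <- internal_forces(mod, structure(list(u = u, v = 0 * u, t = 0),
                                      class = "fem_state"))
  E_mpa <- mod$material$E / 1e6
  sigmaA <- E_mpa * eps * L[2] * L[3]

  face <- abs(m$nodes[, 1] - L[1]) < 1e-9
  expect_equal(-sum(f[face, 1]), sigmaA, tolerance = 1e-6)
  expect_lt(max(abs(sum(f[face, 2])), abs(sum(f[face, 3]))), 1e-6 * sigmaA)
  # interior nodes are in equilibrium
  onb <- m$nodes[, 1] < 1e-9 | face |
    m$nodes[, 2] < 1e-9 | abs(m$nodes[, 2] - L[2]) < 1e-9 |
    m$nodes[, 3] < 1e-9 | abs(m$nodes[, 3] - L[3]) < 1e-9
  expect_lt(max(abs(f[!onb, ])), 1e-6 * sigmaA)
})

test_that("one backward Euler step on a single free node matches the scalar closed form", {
  m <- unit_tet_mesh(pelvis = 1:3)
  mod <- build_fem_model(m)
  Fz <- 2e-4
  f <- matrix(0, 4, 3); f[4, 3] <- Fz
  dt <- 1 / 60
  st <- step_backward_euler(mod, fem_state(mod), f_ext = f, dt = dt,
                            cg_tol = 1e-14)
  # independent scalar model: k = V (lambda + 2 mu) for the z-dof of the
  # apex node of the unit-corner tet; m in tonnes; c = alpha m + beta k
  E <- 0.1; nu <- 0.3
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  k <- (lam + 2 * mu) / 6
  mass <- 1050 * (1 / 6) * 1e-9 / 4 * 1e-3
  alpha <- 1; beta <- 0.01
  c0 <- alpha * mass + beta * k
  dv <- dt * Fz / (mass + dt * c0 + dt^2 * k)
  expect_equal(st$v[4, 3], dv, tolerance = 1e-9)
  expect_equal(st$u[4, 3], dt * dv, tolerance = 1e-9)
  expect_lt(max(abs(st$v[4, 1:2])), 1e-12 * abs(dv))
})

test_that("equilibrium is a fixed point and constraints never drift", {
  me <- small_ellipsoid_mesh()
  mod <- build_fem_model(me)
  st <- fem_state(mod)
  st1 <- step_backward_euler(mod, st)
  expect_true(all(st1$u == 0) && all(st1$v == 0))
  expect_equal(st1$t, 1 / 60)

  set.seed(3)
  st <- fem_state(mod, u = matrix(rnorm(3 * nrow(me$nodes), sd = 0.05), ncol = 3))
  for (i in 1:100) st <- step_backward_euler(mod, st)
  expect_lte(max(abs(st$u[mod$constrained, ])), 1e-10)
})

test_that("unforced damped motion dissipates mechanical energy", {
  me <- small_ellipsoid_mesh()
  mod <- build_fem_model(me)
  up <- matrix(0, nrow(me$nodes), 3)
  up[, 1] <- 0.1 * sin(me$nodes[, 2] / 4)
  st <- fem_state(mod, u = up)
  e <- sum(unlist(fem_energies(mod, st)))
  e0 <- e
  for (i in 1:50) {
    st <- step_backward_euler(mod, st)
    e1 <- attr(st, "strain_J") + attr(st, "kinetic_J")
    expect_lte(e1, e + 1e-12 * e0)  # slack = double-precision floor
    e <- e1
  }
})
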