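# Shared fixtures and independent oracles. Everything here is built in code
# at test time; the oracles deliberately avoid the package's own compiled
# paths.

# the unit-corner tetrahedron (volume 1/6)
unit_tet_mesh <- function(pelvis = 1:3) {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1L), node_sets = list(pelvis = pelvis))
}

# small ellipsoid simulation mesh (roughly 200-300 nodes)
small_ellipsoid_mesh <- function(spacing = 6) {
  tetrahedralize_ellipsoid(c(20, 12, 12), lattice_spacing = spacing)
}

# dense small-strain linear-elastic stiffness, assembled independently in R
# (constant-strain B matrices, Voigt elasticity); 3N x 3N, N/mm, E in MPa
dense_linear_stiffness <- function(mesh, E_mpa = 0.1, nu = 0.3) {
  n <- nrow(mesh$nodes)
  K <- matrix(0, 3 * n, 3 * n)
  lam <- E_mpa * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E_mpa / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  for (e in seq_len(nrow(mesh$tets))) {
    ix <- mesh$tets[e, ]
    p <- mesh$nodes[ix, ]
    Dm <- t(p[2:4, ]) - p[1, ]
    V <- det(Dm) / 6
    G <- rbind(-colSums(solve(Dm)), solve(Dm))  # 4 x 3 shape gradients
    B <- matrix(0, 6, 12)
    for (a in 1:4) {
      b <- G[a, ]
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- b[1]; B[2, c0 + 2] <- b[2]; B[3, c0 + 3] <- b[3]
      B[4, c0 + 1] <- b[2]; B[4, c0 + 2] <- b[1]
      B[5, c0 + 2] <- b[3]; B[5, c0 + 3] <- b[2]
      B[6, c0 + 1] <- b[3]; B[6, c0 + 3] <- b[1]
    }
    Ke <- V * t(B) %*% D %*% B
    dofs <- as.vector(rbind(3 * ix - 2, 3 * ix - 1, 3 * ix))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}

# brute-force point-to-segment distances (oracle for nearest_nodes)
brute_segment_distances <- function(positions, tip, dir, len) {
  tail_pt <- tip - len * dir
  vapply(seq_len(nrow(positions)), function(i) {
    p <- positions[i, ]
    s <- max(0, min(len, sum((p - tail_pt) * dir)))
    sqrt(sum((p - (tail_pt + s * dir))^2))
  }, 1)
}

# rotation about an axis (test-side copy, independent of package internals)
rot_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  ca * diag(3) + sa * rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]),
                            c(-a[2], a[1], 0)) + (1 - ca) * outer(a, a)
}

# small fast phantom + session config used by session-level tests
small_session_config <- function(...) {
  merge <- list(...)
  base <- list(
    duration_s = 2,
    phantom = list(dims = c(64L, 64L, 48L), spacing = c(1, 1, 1),
                   semi_axes = c(20, 12, 12), sigma_s = 0.5, mesh_spacing = 5),
    view = list(width_px = 64L, height_px = 48L, pixel_spacing_mm = 1,
                slab_halfthickness_mm = 2)
  )
  utils::modifyList(base, merge)
}

# a trajectory that keeps the needle far from the phantom
far_trajectory <- function(centre, view, duration = 2) {
  mk <- function(t) list(
    t = t,
    probe = probe_pose(centre, diag(3), view$width_px, view$height_px,
                       view$pixel_spacing_mm, view$slab_halfthickness_mm),
    tip = c(400, 400, 400), dir = c(0, 0, -1))
  trajectory_spec(list(mk(0), mk(duration)), "linear", duration = duration)
}

# straight fast insertion along -x into an ellipsoid phantom centred at C
insertion_trajectory <- function(C, a, view, duration = 2.5, speed = 10) {
  mk <- function(t, tip) list(
    t = t,
    probe = probe_pose(C, diag(3), view$width_px, view$height_px,
                       view$pixel_spacing_mm, view$slab_halfthickness_mm),
    tip = tip, dir = c(-1, 0, 0))
  tip0 <- C + c(a + 5, 0, 0)
  trajectory_spec(list(mk(0, tip0),
                       mk(duration, tip0 + c(-speed * duration, 0, 0))),
                  "linear", duration = duration)
}
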