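test_that("identity-pose reslice reproduces the voxel plane bit-exactly", {
  set.seed(5)
  dat <- array(runif(32 * 24 * 8, 0, 255), c(32, 24, 8))
  v <- scalar_volume(dat)
  pp <- probe_pose(centre = c(16, 12, 2.5), rotation = diag(3),
                   width_px = 32, height_px = 24, pixel_spacing = 1)
  im <- reslice(v, pp)
  # pixel (r, c) -> u = x (column), v = y (row); plane z = 2.5 is slab k = 3
  expect_identical(im$pixels, t(dat[, , 3]))
})

test_that("90-degree poses match the index-permutation oracle bit-exactly", {
  set.seed(6)
  dat <- array(runif(16 * 16 * 16, 0, 255), c(16, 16, 16))
  v <- scalar_volume(dat)
  # u axis -> +y, v axis -> -x, normal -> +z  (90 deg about z)
  R <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  pp <- probe_pose(centre = c(8, 8, 4.5), rotation = R,
                   width_px = 16, height_px = 16, pixel_spacing = 1)
  im <- reslice(v, pp)
  # oracle by direct index arithmetic
  oracle <- matrix(0, 16, 16)
  for (r in 1:16) for (c in 1:16) {
    w <- c(8, 8, 4.5) + R %*% c(c - 0.5 - 8, r - 0.5 - 8, 0)
    oracle[r, c] <- dat[w[1] + 0.5, w[2] + 0.5, w[3] + 0.5]
  }
  expect_identical(im$pixels, oracle)
})

test_that("trilinear reslice is exact for affine intensity fields", {
  dims <- c(24, 20, 16)
  cc <- lapply(dims, function(n) seq_len(n) - 0.5)
  aff <- function(x, y, z) 10 + 0.7 * x - 0.4 * y + 1.1 * z
  dat <- outer(outer(0.7 * cc[[1]], -0.4 * cc[[2]], "+"), 1.1 * cc[[3]], "+") + 10
  v <- scalar_volume(dat)
  R <- rot_about(c(0.3, 1, 0.2), 0.5)
  pp <- probe_pose(centre = dims / 2, rotation = R, width_px = 20,
                   height_px = 16, pixel_spacing = 0.8)
  im <- reslice(v, pp)
  pts <- kbsim:::pixel_world_points(pp)
  expected <- matrix(aff(pts[, 1], pts[, 2], pts[, 3]), 16, 20)
  # only pixels whose interpolation stencil is fully inside the volume
  inb <- matrix(pts[, 1] >= 0.5 & pts[, 1] <= dims[1] - 0.5 &
                  pts[, 2] >= 0.5 & pts[, 2] <= dims[2] - 0.5 &
                  pts[, 3] >= 0.5 & pts[, 3] <= dims[3] - 0.5, 16, 20)
  expect_gt(sum(inb), 100)
  expect_lt(max(abs(im$pixels[inb] - expected[inb])), 1e-9)
})

test_that("poses outside the volume produce background zeros", {
  v <- scalar_volume(array(100, c(8, 8, 8)))
  pp <- probe_pose(centre = c(500, 500, 500), rotation = diag(3),
                   width_px = 8, height_px = 8, pixel_spacing = 1)
  expect_true(all(reslice(v, pp)$pixels == 0))
})

test_that("deformation warp: zero-displacement identity, translation oracle, outside contract", {
  set.seed(8)
  dat <- array(runif(40 * 40 * 20, 0, 255), c(40, 40, 20))
  v <- scalar_volume(dat)
  pp <- probe_pose(centre = c(20, 20, 10), rotation = diag(3),
                   width_px = 30, height_px = 24, pixel_spacing = 1)
  base <- reslice(v, pp)

  mesh <- tet_mesh_block(c(50, 40, 8), c(5L, 4L, 2L), origin = c(-5, 0, 6))
  u0 <- matrix(0, nrow(mesh$nodes), 3)
  expect_identical(warp_with_deformation(v, pp, mesh, u0)$pixels, base$pixels)

  # uniform translation of a mesh covering the whole slice
  d <- c(2.5, -1.5, 0)
  ut <- matrix(d, nrow(mesh$nodes), 3, byrow = TRUE)
  wt <- warp_with_deformation(v, pp, mesh, ut)
  pp2 <- pp; pp2$centre <- pp$centre - d
  expect_lt(max(abs(wt$pixels - reslice(v, pp2)$pixels)), 1e-6)

  # pixels outside the mesh equal the plain reslice
  small <- tetrahedralize_ellipsoid(c(5, 5, 3), 2, centre = c(10, 10, 10))
  us <- matrix(c(1, 0, 0), nrow(small$nodes), 3, byrow = TRUE)
  ws <- warp_with_deformation(v, pp, small, us)
  pts <- kbsim:::pixel_world_points(pp)
  far <- sqrt((pts[, 1] - 10)^2 + (pts[, 2] - 10)^2) > 10
  expect_identical(ws$pixels[matrix(far, 24, 30)], base$pixels[matrix(far, 24, 30)])
  # ... and some pixels inside the mesh did change
  expect_gt(sum(ws$pixels != base$pixels), 0)
})

test_that("needle overlay gates on the slab and matches a per-pixel oracle", {
  v <- scalar_volume(array(128, c(30, 30, 10)))
  pp <- probe_pose(centre = c(15, 15, 5), rotation = diag(3),
                   width_px = 30, height_px = 30, pixel_spacing = 1,
                   slab_halfthickness = 2)
  base <- reslice(v, pp)

  out_of_slab <- needle_state(c(15, 15, 20), c(1, 0, 0), length = 10)
  expect_identical(needle_overlay(base, pp, out_of_slab)$pixels, base$pixels)

  nd <- needle_state(c(22, 15.5, 5.6), c(-1, 0.1, 0.05) / sqrt(1.0125),
                     length = 18)
  echo <- list(amplitude = 200, sigma_mm = 0.6)
  got <- needle_overlay(base, pp, nd, echo)

  # independent per-pixel rasteriser
  R <- pp$rotation
  p1 <- as.numeric(t(R) %*% (nd$tip - pp$centre))
  p0 <- as.numeric(t(R) %*% (nd$tip - nd$length * nd$dir - pp$centre))
  h <- pp$slab_halfthickness
  # clip to |w| <= h
  tt <- sort(c((h - p0[3]) / (p1[3] - p0[3]), (-h - p0[3]) / (p1[3] - p0[3])))
  lo <- max(0, tt[1]); hi <- min(1, tt[2])
  q0 <- p0 + lo * (p1 - p0); q1 <- p0 + hi * (p1 - p0)
  oracle <- base$pixels
  for (r in 1:30) for (c in 1:30) {
    pu <- (c - 0.5 - 15); pv <- (r - 0.5 - 15)
    seg <- q1[1:2] - q0[1:2]
    t_par <- max(0, min(1, sum((c(pu, pv) - q0[1:2]) * seg) / sum(seg^2)))
    cp <- q0[1:2] + t_par * seg
    d2 <- sum((c(pu, pv) - cp)^2)
    if (d2 <= (3 * echo$sigma_mm)^2) {
      w <- q0[3] + t_par * (q1[3] - q0[3])
      oracle[r, c] <- min(255, max(0, oracle[r, c] +
        echo$amplitude * exp(-d2 / (2 * echo$sigma_mm^2)) * (1 - abs(w) / h)))
    }
  }
  expect_equal(got$pixels, oracle, tolerance = 1e-12)
  expect_true(all(got$pixels >= 0 & got$pixels <= 255))
})

test_that("the view pipeline is deterministic", {
  ph <- generate_phantom(phantom_spec(dims = c(32L, 32L, 24L), spacing = c(1, 1, 1),
                                      semi_axes = c(10, 6, 6), mesh_spacing = 3,
                                      seed = 9))
  pp <- probe_pose(ph$spec$centre, diag(3), 32, 24, 1, 2)
  u <- matrix(0.5, nrow(ph$mesh$nodes), 3)
  nd <- needle_state(ph$spec$centre + c(12, 0, 0), c(-1, 0, 0))
  f1 <- needle_overlay(warp_with_deformation(ph$volume, pp, ph$mesh, u), pp, nd)
  f2 <- needle_overlay(warp_with_deformation(ph$volume, pp, ph$mesh, u), pp, nd)
  expect_identical(f1$pixels, f2$pixels)
})
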