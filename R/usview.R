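#' 3D scalar intensity volume
#'
#' Intensities are nominally in `[0, 255]`. The image-to-world map follows
#' the RAS millimetre convention: the centre of 0-based voxel `(i, j, k)`
#' sits at `origin + direction %*% (spacing * (c(i, j, k) + 0.5))`, i.e.
#' `origin` is the world position of the volume corner and voxel centres
#' live at half-integer continuous coordinates.
#'
#' @param data 3D numeric array.
#' @param spacing 3 positive voxel sizes (mm).
#' @param origin world position of the low corner (mm).
#' @param direction 3 x 3 orthonormal direction matrix (columns = world
#'   directions of the i, j, k axes).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          direction = diag(3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stopf("data must be a 3D array")
  if (any(dim(data) < 2L)) stopf("volume must have >= 2 voxels per axis")
  if (!is_num3(spacing) || any(spacing <= 0)) stopf("spacing must be 3 positive lengths")
  direction <- as.matrix(direction)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-8)
    stopf("direction must be orthonormal")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume: %s voxels, spacing %s mm, range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Ultrasound probe pose and slice geometry
#'
#' Maps slice coordinates `(u, v, 0)` (mm, origin at the image centre) to
#' world coordinates: `world = centre + rotation %*% c(u, v, w)`. Column 3
#' of `rotation` is the slice normal; `slab_halfthickness` bounds the
#' out-of-plane band within which the needle echo is visible.
#'
#' @param centre world position of the slice centre (mm).
#' @param rotation 3 x 3 orthonormal matrix (columns: u axis, v axis,
#'   normal).
#' @param width_px,height_px image size in pixels.
#' @param pixel_spacing pixel size (mm).
#' @param slab_halfthickness half-thickness of the visibility slab (mm).
#' @return An object of class `probe_pose`.
#' @export
probe_pose <- function(centre, rotation = diag(3), width_px = 128L,
                       height_px = 96L, pixel_spacing = 1,
                       slab_halfthickness = 2) {
  stopifnot(is_num3(centre))
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stopf("rotation part must be orthonormal")
  if (width_px < 1L || height_px < 1L) stopf("image size must be >= 1 px")
  if (pixel_spacing <= 0) stopf("pixel spacing must be > 0")
  if (slab_halfthickness <= 0) stopf("slab half-thickness must be > 0")
  structure(list(centre = as.numeric(centre), rotation = rotation,
                 width_px = as.integer(width_px), height_px = as.integer(height_px),
                 pixel_spacing = pixel_spacing,
                 slab_halfthickness = slab_halfthickness),
            class = "probe_pose")
}

# world coordinates of every pixel centre (row-major over the H x W grid):
# pixel (r, c) maps to slice coords ((c - 0.5 - W/2) s, (r - 0.5 - H/2) s, 0)
pixel_world_points <- function(pose) {
  s <- pose$pixel_spacing
  u <- (seq_len(pose$width_px) - 0.5 - pose$width_px / 2) * s
  v <- (seq_len(pose$height_px) - 0.5 - pose$height_px / 2) * s
  g <- cbind(rep(u, each = pose$height_px), rep(v, times = pose$width_px), 0)
  sweep(g %*% t(pose$rotation), 2L, pose$centre, "+")
}

# trilinear sampling at world points; outside the volume -> 0. Continuous
# voxel coordinates exactly on a lattice point (to 1e-9) are snapped so
# degenerate interpolation reproduces voxel values bit-exactly.
sample_trilinear <- function(volume, pts) {
  dims <- dim(volume$data)
  rel <- sweep(pts, 2L, volume$origin) %*% volume$direction
  g <- sweep(rel, 2L, volume$spacing, "/") - 0.5
  gr <- round(g)
  snap <- abs(g - gr) < 1e-9
  g[snap] <- gr[snap]
  i0 <- floor(g)
  fr <- g - i0

  val <- numeric(nrow(pts))
  dat <- volume$data
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1L] else 1 - fr[, 1L]) *
      (if (dy) fr[, 2L] else 1 - fr[, 2L]) *
      (if (dz) fr[, 3L] else 1 - fr[, 3L])
    nz_w <- w != 0
    if (!any(nz_w)) next
    ii <- i0[nz_w, 1L] + dx; jj <- i0[nz_w, 2L] + dy; kk <- i0[nz_w, 3L] + dz
    ok <- ii >= 0 & ii < nx & jj >= 0 & jj < ny & kk >= 0 & kk < nz
    if (any(ok)) {
      idx <- which(nz_w)[ok]
      lin <- (kk[ok] * ny + jj[ok]) * nx + ii[ok] + 1
      val[idx] <- val[idx] + w[nz_w][ok] * dat[lin]
    }
  }
  val
}

new_us_image <- function(pixels, pose, t) {
  structure(list(pixels = pixels, pose = pose, t = t), class = "us_image")
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("us_image: %d x %d px at t = %.3f s, range [%.1f, %.1f]\n",
              nrow(x$pixels), ncol(x$pixels), x$t, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Reslice a volume along the probe plane
#'
#' Pixel `(r, c)` samples the volume by trilinear interpolation at the
#' world point of its centre; points outside the volume read 0. With the
#' probe plane aligned to a voxel plane and matching pixel spacing the
#' interpolation weights degenerate and the voxel plane is reproduced
#' exactly.
#'
#' @param volume a [scalar_volume()].
#' @param pose a [probe_pose()].
#' @param t timestamp to stamp on the frame (s).
#' @return A `us_image` (H x W pixel matrix in `[0, 255]`).
#' @export
reslice <- function(volume, pose, t = 0) {
  stopifnot(inherits(volume, "scalar_volume"), inherits(pose, "probe_pose"))
  pts <- pixel_world_points(pose)
  val <- sample_trilinear(volume, pts)
  new_us_image(matrix(val, pose$height_px, pose$width_px), pose, t)
}

# displacement field of the deformed mesh at the slice's pixel world
# points: barycentric interpolation of u over the tet containing the point
# in the DEFORMED configuration; 0 outside (point-location failure is
# "outside", never an error). Exploits the regular pixel grid: candidate
# tets are those straddling the slice plane, and each is tested only
# against the pixels of its own slice-coordinate bounding box. Ties at
# shared faces resolve to the lowest tet index (tets scanned in order,
# first assignment wins). Returns an n_pixels x 3 matrix in the
# pixel_world_points() ordering.
interp_displacement <- function(mesh, u, pts, pose) {
  def <- mesh$nodes + u
  n_pts <- nrow(pts)
  uhat <- matrix(0, n_pts, 3L)
  tets <- mesh$tets
  tol <- 1e-9

  # all deformed nodes in slice coordinates
  sl <- sweep(def, 2L, pose$centre) %*% pose$rotation
  wmin <- pmin(sl[tets[, 1L], 3L], sl[tets[, 2L], 3L],
               sl[tets[, 3L], 3L], sl[tets[, 4L], 3L])
  wmax <- pmax(sl[tets[, 1L], 3L], sl[tets[, 2L], 3L],
               sl[tets[, 3L], 3L], sl[tets[, 4L], 3L])
  cand <- which(wmin <= tol & wmax >= -tol)
  if (!length(cand)) return(uhat)

  s <- pose$pixel_spacing
  W <- pose$width_px; H <- pose$height_px
  # pixel (r, c): u = (c - 0.5 - W/2) s, v = (r - 0.5 - H/2) s
  col_of <- function(uu) uu / s + W / 2 + 0.5
  row_of <- function(vv) vv / s + H / 2 + 0.5
  unassigned <- rep(TRUE, n_pts)

  for (e in cand) {
    ix <- tets[e, ]
    sv <- sl[ix, , drop = FALSE]
    c0 <- max(1L, ceiling(col_of(min(sv[, 1L])) - 1e-9))
    c1 <- min(W, floor(col_of(max(sv[, 1L])) + 1e-9))
    r0 <- max(1L, ceiling(row_of(min(sv[, 2L])) - 1e-9))
    r1 <- min(H, floor(row_of(max(sv[, 2L])) + 1e-9))
    if (c0 > c1 || r0 > r1) next
    # linear indices into the column-major H x W pixel grid
    pix <- as.vector(outer(r0:r1, (c0:c1 - 1L) * H, "+"))
    pix <- pix[unassigned[pix]]
    if (!length(pix)) next
    vs <- def[ix, , drop = FALSE]
    A <- cbind(vs[2L, ] - vs[1L, ], vs[3L, ] - vs[1L, ], vs[4L, ] - vs[1L, ])
    # explicit cofactor inverse; degenerate tets are skipped
    co <- cbind(c(A[2,2]*A[3,3]-A[2,3]*A[3,2], A[1,3]*A[3,2]-A[1,2]*A[3,3],
                  A[1,2]*A[2,3]-A[1,3]*A[2,2]),
                c(A[2,3]*A[3,1]-A[2,1]*A[3,3], A[1,1]*A[3,3]-A[1,3]*A[3,1],
                  A[1,3]*A[2,1]-A[1,1]*A[2,3]),
                c(A[2,1]*A[3,2]-A[2,2]*A[3,1], A[1,2]*A[3,1]-A[1,1]*A[3,2],
                  A[1,1]*A[2,2]-A[1,2]*A[2,1]))
    detA <- A[1,1]*co[1,1] + A[2,1]*co[2,1] + A[3,1]*co[3,1]
    if (abs(detA) < 1e-12) next
    Ai <- t(co) / detA
    rel <- sweep(pts[pix, , drop = FALSE], 2L, vs[1L, ])
    lam <- rel %*% t(Ai)
    l0 <- 1 - rowSums(lam)
    inside <- lam[, 1L] >= -tol & lam[, 2L] >= -tol & lam[, 3L] >= -tol &
      l0 >= -tol
    if (!any(inside)) next
    hit <- pix[inside]
    w <- cbind(l0[inside], lam[inside, , drop = FALSE])
    uhat[hit, ] <- w %*% u[ix, , drop = FALSE]
    unassigned[hit] <- FALSE
  }
  uhat
}

#' Reslice with tissue deformation warping
#'
#' Backward warping: each pixel's world point `x` is pulled back to the
#' material point `x - u_hat(x)`, where `u_hat` interpolates the nodal
#' displacements barycentrically over the deformed mesh (zero outside the
#' mesh), and the volume is sampled there as in [reslice()]. With `u = 0`
#' the output is bit-identical to the plain reslice.
#'
#' @param volume a [scalar_volume()].
#' @param pose a [probe_pose()].
#' @param mesh a [tet_mesh()].
#' @param u N x 3 nodal displacements (mm).
#' @param t timestamp (s).
#' @return A `us_image`.
#' @export
warp_with_deformation <- function(volume, pose, mesh, u, t = 0) {
  stopifnot(inherits(volume, "scalar_volume"), inherits(pose, "probe_pose"),
            inherits(mesh, "tet_mesh"))
  u <- as.matrix(u)
  stopifnot(nrow(u) == nrow(mesh$nodes), ncol(u) == 3L)
  pts <- pixel_world_points(pose)
  uhat <- interp_displacement(mesh, u, pts, pose)
  val <- sample_trilinear(volume, pts - uhat)
  new_us_image(matrix(val, pose$height_px, pose$width_px), pose, t)
}

#' Fuse a synthetic needle echo into a frame
#'
#' The needle segment is transformed to slice coordinates; the portion
#' within the visibility slab (`|w| <= slab_halfthickness`) is rasterised
#' with a Gaussian transverse profile and a linear out-of-plane falloff:
#' pixels within `3 sigma` of the in-plane segment gain
#' `A exp(-d^2 / (2 sigma^2)) (1 - |w|/h)`, additively, clamped to
#' `[0, 255]`. The overlay is applied after warping: the physical needle is
#' rigid and its echo is never deformed.
#'
#' @param image a `us_image`.
#' @param pose the generating [probe_pose()].
#' @param needle a [needle_state()].
#' @param echo list with `amplitude` (additive intensity, >= 0) and
#'   `sigma_mm` (transverse Gaussian width, > 0).
#' @return A `us_image`.
#' @export
needle_overlay <- function(image, pose, needle,
                           echo = list(amplitude = 200, sigma_mm = 0.6)) {
  stopifnot(inherits(image, "us_image"), inherits(pose, "probe_pose"),
            inherits(needle, "needle_state"))
  A <- echo$amplitude; sigma <- echo$sigma_mm
  stopifnot(A >= 0, sigma > 0)
  if (A == 0) return(image)

  tail_pt <- needle$tip - needle$length * needle$dir
  p0 <- as.numeric(crossprod(pose$rotation, tail_pt - pose$centre))
  p1 <- as.numeric(crossprod(pose$rotation, needle$tip - pose$centre))
  h <- pose$slab_halfthickness

  # clip parameter range [0,1] to |w| <= h (w is linear in t)
  w0 <- p0[3L]; w1 <- p1[3L]
  lo <- 0; hi <- 1
  dw <- w1 - w0
  for (bound in c(1, -1)) {
    # constraint bound*w(t) <= h
    c0 <- bound * w0; cd <- bound * dw
    if (abs(cd) < 1e-15) {
      if (c0 > h) return(image)
    } else {
      tb <- (h - c0) / cd
      if (cd > 0) hi <- min(hi, tb) else lo <- max(lo, tb)
    }
  }
  if (lo > hi) return(image)
  q0 <- p0 + lo * (p1 - p0)
  q1 <- p0 + hi * (p1 - p0)

  s <- pose$pixel_spacing
  W <- pose$width_px; H <- pose$height_px
  ug <- (seq_len(W) - 0.5 - W / 2) * s
  vg <- (seq_len(H) - 0.5 - H / 2) * s
  pu <- matrix(ug, H, W, byrow = TRUE)
  pv <- matrix(vg, H, W)

  seg <- q1[1:2] - q0[1:2]
  len2 <- sum(seg^2)
  du <- pu - q0[1L]; dv <- pv - q0[2L]
  tpar <- if (len2 < 1e-15) matrix(0, H, W) else
    clamp((du * seg[1L] + dv * seg[2L]) / len2, 0, 1)
  dx <- du - tpar * seg[1L]
  dy <- dv - tpar * seg[2L]
  d2 <- dx^2 + dy^2
  wstar <- q0[3L] + tpar * (q1[3L] - q0[3L])
  gain <- A * exp(-d2 / (2 * sigma^2)) * (1 - abs(wstar) / h)
  gain[d2 > (3 * sigma)^2] <- 0
  px <- clamp(image$pixels + gain, 0, 255)
  new_us_image(px, image$pose, image$t)
}

#' Write a frame as an 8-bit grayscale PNG
#'
#' @param image a `us_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(image, path) {
  stopifnot(inherits(image, "us_image"))
  px <- round(clamp(image$pixels, 0, 255)) / 255
  png::writePNG(px, path)
  invisible(path)
}
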