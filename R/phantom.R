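#' Synthetic kidney phantom specification
#'
#' Describes the speckled ultrasound-like phantom that stands in for a
#' patient 3D acquisition plus expert segmentation: an ellipsoidal kidney
#' (bright thin capsule, mid-echogenic cortex, echogenic central sinus at
#' half the semi-axes) in a darker background, with unit-mean
#' multiplicative speckle. The default geometry, 128 x 128 x 96 voxels at
#' 0.8 mm with semi-axes 45 x 25 x 25 mm, gives reslices resembling a
#' renal long-axis view.
#'
#' @param dims volume size in voxels (>= 16 per axis).
#' @param spacing voxel size (mm).
#' @param semi_axes kidney semi-axes (mm).
#' @param centre kidney centre (mm, world); default = volume centre.
#' @param orientation 3 x 3 rotation of the kidney axes.
#' @param echogenicity named means in `[0, 255]`: `background`, `cortex`,
#'   `sinus`, `capsule`.
#' @param sigma_s speckle strength (0 disables speckle; see [speckle()]).
#' @param mesh_spacing lattice spacing for the matched tetrahedral mesh
#'   (mm); `NULL` uses the element-count heuristic of
#'   [tetrahedralize_ellipsoid()].
#' @param seed integer RNG seed governing all stochastic generation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(128L, 128L, 96L), spacing = c(0.8, 0.8, 0.8),
                         semi_axes = c(45, 25, 25), centre = NULL,
                         orientation = diag(3),
                         echogenicity = c(background = 60, cortex = 110,
                                          sinus = 170, capsule = 220),
                         sigma_s = 0.5, mesh_spacing = NULL, seed = 1L) {
  dims <- as.integer(dims)
  if (any(dims < 16L)) stopf("volume must be >= 16 voxels per axis")
  stopifnot(is_num3(spacing), all(spacing > 0), is_num3(semi_axes),
            all(semi_axes > 0), sigma_s >= 0)
  extent <- dims * spacing
  if (is.null(centre)) centre <- extent / 2
  orientation <- as.matrix(orientation)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-8)
    stopf("orientation must be orthonormal")
  ech <- echogenicity
  if (is.null(names(ech)) || !all(c("background", "cortex", "sinus", "capsule")
                                  %in% names(ech)))
    stopf("echogenicity needs named entries background, cortex, sinus, capsule")
  if (any(ech < 0) || any(ech > 255)) stopf("echogenicity must lie in [0, 255]")
  # world-axis half extent of the rotated ellipsoid
  half <- sqrt((orientation^2) %*% semi_axes^2)
  if (any(centre - half < 0) || any(centre + half > extent))
    stopf("kidney does not fit inside the volume")
  structure(list(dims = dims, spacing = as.numeric(spacing),
                 semi_axes = as.numeric(semi_axes), centre = as.numeric(centre),
                 orientation = orientation, echogenicity = ech,
                 sigma_s = sigma_s, mesh_spacing = mesh_spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Unit-mean multiplicative speckle
#'
#' Fully developed ultrasound speckle is Rayleigh distributed; each value
#' is multiplied by `1 + sigma_s * (X / E[X] - 1)` with `X` Rayleigh, a
#' unit-mean factor whose standard deviation scales linearly with
#' `sigma_s` (`sigma_s = 0` is the exact identity). Results are clamped to
#' `[0, 255]`, a documented bias at very high intensities. Seeded and
#' reproducible; the caller's RNG state is left untouched.
#'
#' @param values numeric vector or array of intensities.
#' @param sigma_s speckle strength (>= 0).
#' @param seed integer seed.
#' @return values with speckle applied, same shape.
#' @export
speckle <- function(values, sigma_s, seed = 1L) {
  if (sigma_s < 0) stopf("sigma_s must be >= 0")
  if (sigma_s == 0) return(values)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- sqrt(-2 * log(runif(length(values))))       # Rayleigh, scale 1
  factor <- 1 + sigma_s * (x / sqrt(pi / 2) - 1)   # unit mean
  out <- clamp(values * factor, 0, 255)
  if (!is.null(dim(values))) dim(out) <- dim(values)
  out
}

#' Generate the synthetic phantom volume and matched mesh
#'
#' Builds the labelled kidney volume described by the spec (background,
#' cortex shell, sinus co-ellipsoid at half the semi-axes, one-voxel bright
#' capsule rim), applies speckle, and tetrahedralises the same ellipsoid in
#' the same world frame so mesh and voxel kidney are registered; the
#' `"pelvis"` node set sits at the pole of the negative first kidney axis.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [scalar_volume()]) and `mesh`
#'   (a [tet_mesh()]), plus the `spec` (which records the seed).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims; sp <- spec$spacing
  # voxel-centre world coordinates, axis-aligned volume at the origin corner
  xs <- (seq_len(dims[1L]) - 0.5) * sp[1L]
  ys <- (seq_len(dims[2L]) - 0.5) * sp[2L]
  zs <- (seq_len(dims[3L]) - 0.5) * sp[3L]

  O <- spec$orientation
  ax <- spec$semi_axes
  # kidney-frame coordinates q = O^T (p - c); phi = sum (q_axis / a_axis)^2,
  # accumulated axis by axis to avoid materialising full coordinate arrays
  phi_at <- function(scale) {
    acc <- array(0, dims)
    for (axis in 1:3) {
      qa <- (outer(outer((xs - spec$centre[1L]) * O[1L, axis],
                         (ys - spec$centre[2L]) * O[2L, axis], "+"),
                   (zs - spec$centre[3L]) * O[3L, axis], "+")) / (ax[axis] * scale)
      acc <- acc + qa^2
    }
    acc
  }
  phi <- phi_at(1)
  phi_sinus <- phi_at(0.5)

  ech <- spec$echogenicity
  vol <- array(ech[["background"]], dims)
  kidney <- phi <= 1
  vol[kidney] <- ech[["cortex"]]
  vol[phi_sinus <= 1] <- ech[["sinus"]]
  # one-voxel capsule rim at the outer surface
  rim_depth <- mean(sp) / min(ax)
  vol[kidney & sqrt(phi) >= 1 - rim_depth] <- ech[["capsule"]]

  vol <- speckle(vol, spec$sigma_s, spec$seed)
  volume <- scalar_volume(vol, sp, origin = c(0, 0, 0))

  mesh <- tetrahedralize_ellipsoid(ax, lattice_spacing = spec$mesh_spacing,
                                   centre = c(0, 0, 0),
                                   pelvis_axis = c(-1, 0, 0))
  nodes <- mesh$nodes %*% t(O)
  nodes <- sweep(nodes, 2L, spec$centre, "+")
  mesh$nodes <- nodes

  list(volume = volume, mesh = mesh, spec = spec)
}

#' Scripted probe and needle trajectory
#'
#' Keyframed poses standing in for the tracked probe and the haptic-device
#' needle. Between keyframes, positions interpolate linearly, probe
#' rotations by normalised-linear quaternion interpolation and needle
#' directions by normalised-linear vector interpolation; `"hold"` returns
#' the earlier keyframe. The needle tip velocity is the analytic derivative
#' of the interpolant.
#'
#' @param keyframes list of keyframes, each a list with `t` (s), `probe`
#'   (a [probe_pose()]), `tip` (mm), `dir` (unit, tip-ward).
#' @param interpolation `"linear"` or `"hold"`.
#' @param duration total duration (s); default = last keyframe time.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(keyframes, interpolation = c("linear", "hold"),
                            duration = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(keyframes) >= 1L)
  times <- vapply(keyframes, function(k) k$t, 1)
  if (any(diff(times) <= 0)) stopf("keyframe times must be strictly increasing")
  for (k in keyframes) {
    stopifnot(inherits(k$probe, "probe_pose"), is_num3(k$tip), is_num3(k$dir))
  }
  if (is.null(duration)) duration <- times[length(times)]
  if (duration < times[length(times)])
    stopf("duration %.3g shorter than last keyframe %.3g", duration,
          times[length(times)])
  structure(list(keyframes = keyframes, times = times,
                 interpolation = interpolation, duration = duration),
            class = "trajectory_spec")
}

nlerp_quat <- function(q1, q2, f) {
  if (sum(q1 * q2) < 0) q2 <- -q2
  q <- (1 - f) * q1 + f * q2
  q / sqrt(sum(q^2))
}

#' Probe and needle poses at a time point
#'
#' @param traj a [trajectory_spec()].
#' @param t time (s) in `[0, duration]`.
#' @return list with `probe` (a [probe_pose()]) and `needle`
#'   (a [needle_state()], phase `free`; the session loop owns the phase).
#' @export
poses_at <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory_spec"))
  if (t < traj$times[1L] - 1e-12 || t > traj$duration + 1e-12)
    stopf("t = %.6g outside trajectory span [%.6g, %.6g]", t, traj$times[1L],
          traj$duration)
  kf <- traj$keyframes
  nk <- length(kf)
  i <- findInterval(t, traj$times, rightmost.closed = FALSE)
  i <- max(1L, min(i, nk))
  if (i == nk || traj$interpolation == "hold") {
    k <- kf[[i]]
    vel <- c(0, 0, 0)
    if (traj$interpolation == "linear" && nk > 1L && i == nk) {
      km <- kf[[i - 1L]]
      vel <- (k$tip - km$tip) / (traj$times[i] - traj$times[i - 1L])
    }
    needle <- needle_state(k$tip, k$dir, tip_velocity = vel)
    return(list(probe = k$probe, needle = needle))
  }
  k1 <- kf[[i]]; k2 <- kf[[i + 1L]]
  dt_seg <- traj$times[i + 1L] - traj$times[i]
  f <- (t - traj$times[i]) / dt_seg

  tip <- (1 - f) * k1$tip + f * k2$tip
  vel <- (k2$tip - k1$tip) / dt_seg
  dir <- normalize((1 - f) * k1$dir + f * k2$dir)
  centre <- (1 - f) * k1$probe$centre + f * k2$probe$centre
  q <- nlerp_quat(rot_to_quat(k1$probe$rotation), rot_to_quat(k2$probe$rotation), f)
  probe <- k1$probe
  probe$centre <- centre
  probe$rotation <- quat_to_rot(q)
  list(probe = probe,
       needle = needle_state(tip, dir, tip_velocity = vel))
}

#' Canonical "scan, aim, insert, retract" trajectory
#'
#' A 10 s scripted biopsy session against a phantom: the probe sweeps onto
#' the kidney long-axis plane (0-2.5 s), the needle lines up on the
#' negative-x insertion axis (2.5-3.5 s), advances at 5 mm/s for 30 mm
#' (3.5-9.5 s, puncturing the capsule on the way), then retracts clear of
#' the surface (9.5-10 s).
#'
#' @param spec the [phantom_spec()] the session runs against (fixes the
#'   kidney centre and surface position).
#' @param view list with `width_px`, `height_px`, `pixel_spacing_mm`,
#'   `slab_halfthickness_mm` for the probe.
#' @return A [trajectory_spec()] of duration 10 s.
#' @export
canonical_insertion_trajectory <- function(spec,
                                           view = list(width_px = 128L,
                                                       height_px = 96L,
                                                       pixel_spacing_mm = 1,
                                                       slab_halfthickness_mm = 2)) {
  stopifnot(inherits(spec, "phantom_spec"))
  C <- spec$centre
  a <- spec$semi_axes[1L]
  mk_probe <- function(centre) probe_pose(
    centre, diag(3), view$width_px, view$height_px, view$pixel_spacing_mm,
    view$slab_halfthickness_mm)
  dirn <- c(-1, 0, 0)
  tip0 <- C + c(a + 25, 0, 0)   # parked clear of the kidney
  tip_aim <- C + c(a + 5, 0, 0) # 5 mm short of the capsule
  tip_in <- tip_aim + 30 * dirn # 30 mm advance at 5 mm/s
  keyframes <- list(
    list(t = 0, probe = mk_probe(C + c(0, 0, -10)), tip = tip0, dir = dirn),
    list(t = 2.5, probe = mk_probe(C), tip = tip0, dir = dirn),
    list(t = 3.5, probe = mk_probe(C), tip = tip_aim, dir = dirn),
    list(t = 9.5, probe = mk_probe(C), tip = tip_in, dir = dirn),
    list(t = 10, probe = mk_probe(C), tip = tip0, dir = dirn)
  )
  trajectory_spec(keyframes, "linear", duration = 10)
}
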