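#' Tetrahedralise an ellipsoid on a body-centred cubic lattice
#'
#' Procedural stand-in for a patient-specific kidney mesh: lattice points of
#' a body-centred cubic (BCC) grid inside the ellipsoid are connected with
#' the standard BCC tetrahedral stencil (12 tets per lattice cube, each of
#' volume `spacing^3 / 12`); tetrahedra with all four vertices inside the
#' ellipsoid are kept and the resulting boundary nodes are snapped radially
#' onto the analytic surface, so the mesh volume converges to the analytic
#' ellipsoid volume as the lattice is refined.
#'
#' A `"pelvis"` node set is auto-populated with the surface nodes inside a
#' polar cap (default: within 25 degrees of the pole on the negative-x
#' semi-axis), standing in for the renal-pelvis Dirichlet region.
#'
#' @param semi_axes 3 positive semi-axis lengths (mm).
#' @param lattice_spacing BCC lattice spacing (mm); must not exceed the
#'   smallest semi-axis. `NULL` (default) picks the spacing that targets
#'   roughly 2600 elements, the scale of a decimated clinical kidney mesh.
#' @param centre ellipsoid centre (mm).
#' @param pelvis_axis direction of the pole defining the pelvis cap.
#' @param pelvis_angle_deg half-angle of the pelvis cap (degrees).
#' @return A [tet_mesh()] with a non-empty `"pelvis"` node set.
#' @examples
#' m <- tetrahedralize_ellipsoid(c(10, 10, 10), lattice_spacing = 2.5)
#' validate_mesh(m)
#' @export
tetrahedralize_ellipsoid <- function(semi_axes, lattice_spacing = NULL,
                                     centre = c(0, 0, 0),
                                     pelvis_axis = c(-1, 0, 0),
                                     pelvis_angle_deg = 25) {
  if (!is_num3(semi_axes) || any(semi_axes <= 0))
    stopf("semi_axes must be 3 positive lengths")
  if (is.null(lattice_spacing)) {
    vol <- 4 / 3 * pi * prod(semi_axes)
    # 12 tets of volume h^3/12 per lattice cube, targeting ~2600 elements
    lattice_spacing <- (12 * vol / 2600)^(1 / 3)
  }
  if (lattice_spacing <= 0) stopf("lattice_spacing must be positive")
  if (lattice_spacing > min(semi_axes))
    stopf("degenerate mesh: lattice_spacing %.3g exceeds smallest semi-axis %.3g",
          lattice_spacing, min(semi_axes))

  h <- lattice_spacing
  nmax <- ceiling(semi_axes / h) + 1L
  ir <- -nmax[1L]:nmax[1L]; jr <- -nmax[2L]:nmax[2L]; kr <- -nmax[3L]:nmax[3L]
  ni <- length(ir); nj <- length(jr); nk <- length(kr)

  # point id encoding: (type, i, j, k) with type 0 = lattice corner,
  # 1 = cell centre (centre of cell whose low corner is (i, j, k))
  enc <- function(type, i, j, k) {
    (((k - kr[1L]) * (nj + 1L) + (j - jr[1L])) * (ni + 1L) + (i - ir[1L])) * 2L +
      type + 1L
  }
  coord_of <- function(type, i, j, k) {
    cbind(centre[1L] + (i + 0.5 * type) * h,
          centre[2L] + (j + 0.5 * type) * h,
          centre[3L] + (k + 0.5 * type) * h)
  }

  cells <- expand.grid(i = ir[-ni], j = jr[-nj], k = kr[-nk])
  ci <- cells$i; cj <- cells$j; ck <- cells$k

  tet_block <- function(c1, c2, A, B, C, D) {
    rbind(cbind(c1, c2, A, B), cbind(c1, c2, B, C),
          cbind(c1, c2, C, D), cbind(c1, c2, D, A))
  }
  # +x faces (between cell (i,j,k) and (i+1,j,k)); valid when i+1 is a cell
  okx <- ci + 1L <= ir[ni - 1L]
  tx <- with(list(i = ci[okx], j = cj[okx], k = ck[okx]), {
    tet_block(enc(1L, i, j, k), enc(1L, i + 1L, j, k),
              enc(0L, i + 1L, j, k), enc(0L, i + 1L, j + 1L, k),
              enc(0L, i + 1L, j + 1L, k + 1L), enc(0L, i + 1L, j, k + 1L))
  })
  oky <- cj + 1L <= jr[nj - 1L]
  ty <- with(list(i = ci[oky], j = cj[oky], k = ck[oky]), {
    tet_block(enc(1L, i, j, k), enc(1L, i, j + 1L, k),
              enc(0L, i, j + 1L, k), enc(0L, i + 1L, j + 1L, k),
              enc(0L, i + 1L, j + 1L, k + 1L), enc(0L, i, j + 1L, k + 1L))
  })
  okz <- ck + 1L <= kr[nk - 1L]
  tz <- with(list(i = ci[okz], j = cj[okz], k = ck[okz]), {
    tet_block(enc(1L, i, j, k), enc(1L, i, j, k + 1L),
              enc(0L, i, j, k + 1L), enc(0L, i + 1L, j, k + 1L),
              enc(0L, i + 1L, j + 1L, k + 1L), enc(0L, i, j + 1L, k + 1L))
  })
  tets_enc <- rbind(tx, ty, tz)

  ids <- sort(unique(as.vector(tets_enc)))
  # decode ids back to coordinates
  dec <- ids - 1L
  type <- dec %% 2L
  rest <- dec %/% 2L
  di <- rest %% (ni + 1L) + ir[1L]
  rest <- rest %/% (ni + 1L)
  dj <- rest %% (nj + 1L) + jr[1L]
  dk <- rest %/% (nj + 1L) + kr[1L]
  pts <- coord_of(type, di, dj, dk)

  phi_of <- function(p)
    ((p[, 1L] - centre[1L]) / semi_axes[1L])^2 +
    ((p[, 2L] - centre[2L]) / semi_axes[2L])^2 +
    ((p[, 3L] - centre[3L]) / semi_axes[3L])^2
  phi <- phi_of(pts)

  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  tets_local <- matrix(remap[tets_enc], nrow(tets_enc), 4L)
  # keep tetrahedra whose centroid lies inside the ellipsoid; boundary nodes
  # (inside or slightly outside) are snapped onto the surface afterwards
  cen <- (pts[tets_local[, 1L], , drop = FALSE] + pts[tets_local[, 2L], , drop = FALSE] +
            pts[tets_local[, 3L], , drop = FALSE] + pts[tets_local[, 4L], , drop = FALSE]) / 4
  keep <- phi_of(cen) <= 1 + 1e-12
  if (!any(keep))
    stopf("degenerate mesh: lattice_spacing %.3g too coarse for semi-axes (%s)",
          h, paste(signif(semi_axes, 3), collapse = ", "))
  tets_local <- tets_local[keep, , drop = FALSE]

  used <- sort(unique(as.vector(tets_local)))
  remap2 <- integer(length(ids))
  remap2[used] <- seq_along(used)
  nodes <- pts[used, , drop = FALSE]
  tets <- matrix(remap2[tets_local], nrow(tets_local), 4L)

  # normalise orientation before snapping so the inversion guard below sees
  # true inversions only
  vols0 <- tet_volumes_raw(nodes, tets)
  inv <- vols0 < 0
  tmp <- tets[inv, 3L]; tets[inv, 3L] <- tets[inv, 4L]; tets[inv, 4L] <- tmp

  # snap boundary nodes radially onto the ellipsoid surface; relax the
  # projection of any node whose elements would collapse below 5% of their
  # lattice volume, so no slivers (or inversions) are introduced
  surf <- unique(as.vector(surface_triangles(tets)))
  phi_used <- phi[used]
  snap_ok <- surf[phi_used[surf] >= 0.2]  # never pull near-centre nodes
  target <- nodes
  d <- sweep(nodes[snap_ok, , drop = FALSE], 2L, centre)
  target[snap_ok, ] <- sweep(d / sqrt(phi_used[snap_ok]), 2L, centre, "+")
  snapped <- target
  vols_pre <- tet_volumes_raw(nodes, tets)
  # nodes whose lattice position lay outside the ellipsoid stay pinned on
  # the surface (the mesh never pokes past the analytic boundary); flattened
  # or inverted elements are repaired by relaxing their interior nodes back
  # toward the lattice
  relaxable <- phi_used < 1
  for (iter in 1:30) {
    vols <- tet_volumes_raw(snapped, tets)
    bad <- vols <= 0.05 * vols_pre
    if (!any(bad)) break
    bad_nodes <- unique(as.vector(tets[bad, , drop = FALSE]))
    bad_nodes <- bad_nodes[relaxable[bad_nodes]]
    if (!length(bad_nodes)) break
    snapped[bad_nodes, ] <- 0.5 * (snapped[bad_nodes, , drop = FALSE] +
                                     nodes[bad_nodes, , drop = FALSE])
  }
  if (any(tet_volumes_raw(snapped, tets) <= 1e-12)) snapped <- nodes

  mesh <- tet_mesh(snapped, tets)
  mesh$node_sets$pelvis <- pelvis_cap_nodes(mesh, centre, pelvis_axis,
                                            pelvis_angle_deg)
  mesh
}

# surface nodes within a polar cap of the given axis; falls back to the
# single surface node closest to the pole so the set is never empty
pelvis_cap_nodes <- function(mesh, centre, axis, angle_deg) {
  axis <- normalize(axis)
  surf <- sort(unique(as.vector(mesh$surface_tris)))
  d <- sweep(mesh$nodes[surf, , drop = FALSE], 2L, centre)
  dn <- d / sqrt(rowSums(d^2))
  cosang <- dn %*% axis
  sel <- surf[cosang >= cos(angle_deg * pi / 180)]
  if (!length(sel)) sel <- surf[which.max(cosang)]
  sort(sel)
}

#' Tetrahedral block mesh
#'
#' Regular grid over an axis-aligned box, each cube split into 6 tetrahedra
#' (Kuhn subdivision). Used for patch tests and as a simple deformable slab.
#'
#' @param lengths box edge lengths (mm).
#' @param divisions number of cells per axis (3 integers >= 1).
#' @param origin low corner of the box (mm).
#' @return A [tet_mesh()] (no node sets attached).
#' @export
tet_mesh_block <- function(lengths, divisions = c(2L, 2L, 2L),
                           origin = c(0, 0, 0)) {
  stopifnot(is_num3(lengths), all(lengths > 0), all(divisions >= 1))
  nd <- as.integer(divisions) + 1L
  xs <- seq(origin[1L], origin[1L] + lengths[1L], length.out = nd[1L])
  ys <- seq(origin[2L], origin[2L] + lengths[2L], length.out = nd[2L])
  zs <- seq(origin[3L], origin[3L] + lengths[3L], length.out = nd[3L])
  g <- expand.grid(x = xs, y = ys, z = zs)
  nodes <- as.matrix(g)
  vid <- function(i, j, k) (k - 1L) * nd[1L] * nd[2L] + (j - 1L) * nd[1L] + i
  cells <- expand.grid(i = seq_len(nd[1L] - 1L), j = seq_len(nd[2L] - 1L),
                       k = seq_len(nd[3L] - 1L))
  v000 <- vid(cells$i, cells$j, cells$k)
  v100 <- vid(cells$i + 1L, cells$j, cells$k)
  v010 <- vid(cells$i, cells$j + 1L, cells$k)
  v110 <- vid(cells$i + 1L, cells$j + 1L, cells$k)
  v001 <- vid(cells$i, cells$j, cells$k + 1L)
  v101 <- vid(cells$i + 1L, cells$j, cells$k + 1L)
  v011 <- vid(cells$i, cells$j + 1L, cells$k + 1L)
  v111 <- vid(cells$i + 1L, cells$j + 1L, cells$k + 1L)
  tets <- rbind(cbind(v000, v100, v110, v111), cbind(v000, v110, v010, v111),
                cbind(v000, v010, v011, v111), cbind(v000, v011, v001, v111),
                cbind(v000, v001, v101, v111), cbind(v000, v101, v100, v111))
  tet_mesh(nodes, tets)
}
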