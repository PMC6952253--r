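#' Tetrahedral mesh container
#'
#' Rest-configuration tetrahedral mesh used by the deformation model. Node
#' positions are in millimetres, world frame. Tetrahedra are stored 1-based
#' (R convention); file readers convert from the on-disk convention. Every
#' tetrahedron is kept in positive orientation:
#' `det(b - a, c - a, d - a) > 0`.
#'
#' @param nodes numeric N x 3 matrix of rest positions (mm).
#' @param tets integer M x 4 matrix of node indices (1-based).
#' @param node_sets named list of integer index vectors; meshes used for
#'   simulation must carry a non-empty `"pelvis"` set (the Dirichlet region
#'   corresponding to the renal pelvis).
#' @param fix_orientation reorder inverted tetrahedra to positive volume
#'   instead of failing.
#' @return An object of class `tet_mesh` with fields `nodes`, `tets`,
#'   `node_sets` and the derived boundary triangle list `surface_tris`.
#' @examples
#' m <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'               matrix(1:4, 1))
#' tet_volumes(m) # 1/6
#' @export
tet_mesh <- function(nodes, tets, node_sets = list(), fix_orientation = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stopf("nodes must be N x 3, got %d columns", ncol(nodes))
  if (ncol(tets) != 4L) stopf("tets must be M x 4, got %d columns", ncol(tets))
  n <- nrow(nodes)
  if (any(tets < 1L) || any(tets > n))
    stopf("tet node index out of range [1, %d]", n)
  if (anyNA(nodes) || any(!is.finite(nodes))) stopf("non-finite node coordinates")
  key <- paste(round(nodes[, 1L], 9L), round(nodes[, 2L], 9L),
               round(nodes[, 3L], 9L))
  if (anyDuplicated(key))
    stopf("duplicate nodes (coincident within 1e-9 mm)")

  vols <- tet_volumes_raw(nodes, tets)
  if (any(vols < 0)) {
    if (!fix_orientation)
      stopf("%d inverted tetrahedra (negative volume)", sum(vols < 0))
    inv <- vols < 0
    tmp <- tets[inv, 3L]
    tets[inv, 3L] <- tets[inv, 4L]
    tets[inv, 4L] <- tmp
  }

  node_sets <- lapply(node_sets, function(ix) {
    ix <- as.integer(ix)
    if (length(ix) && (min(ix) < 1L || max(ix) > n))
      stopf("node_set index out of range [1, %d]", n)
    sort(unique(ix))
  })

  structure(
    list(nodes = nodes, tets = tets, node_sets = node_sets,
         surface_tris = surface_triangles(tets)),
    class = "tet_mesh"
  )
}

# Signed volumes without validation (used during construction)
tet_volumes_raw <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE] - a
  c_ <- nodes[tets[, 3L], , drop = FALSE] - a
  d <- nodes[tets[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c_[, 2L] * d[, 3L] - c_[, 3L] * d[, 2L]) +
     b[, 2L] * (c_[, 3L] * d[, 1L] - c_[, 1L] * d[, 3L]) +
     b[, 3L] * (c_[, 1L] * d[, 2L] - c_[, 2L] * d[, 1L])) / 6
}

#' Signed tetrahedron volumes
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of signed volumes (mm^3), positive for a valid mesh.
#' @export
tet_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  tet_volumes_raw(mesh$nodes, mesh$tets)
}

# Boundary faces: triangles belonging to exactly one tetrahedron, wound
# outward (consistent with positive tet orientation).
surface_triangles <- function(tets) {
  if (nrow(tets) == 0L) return(matrix(integer(), 0L, 3L))
  # faces opposite each node, wound so the outward normal points away from
  # the remaining node when the tet has positive orientation
  f <- rbind(
    tets[, c(2L, 3L, 4L), drop = FALSE],
    tets[, c(1L, 4L, 3L), drop = FALSE],
    tets[, c(1L, 2L, 4L), drop = FALSE],
    tets[, c(1L, 3L, 2L), drop = FALSE]
  )
  lo <- pmin(f[, 1L], f[, 2L], f[, 3L])
  hi <- pmax(f[, 1L], f[, 2L], f[, 3L])
  mid <- f[, 1L] + f[, 2L] + f[, 3L] - lo - hi
  key <- paste(lo, mid, hi)
  cnt <- table(key)
  f[cnt[key] == 1L, , drop = FALSE]
}

#' Mesh quality report
#'
#' Counts and volume statistics used to gate simulation entry points:
#' meshes with inverted or degenerate elements are rejected by
#' [build_fem_model()].
#'
#' @param mesh a [tet_mesh()].
#' @param degenerate_tol volume below which a tetrahedron counts as
#'   degenerate (mm^3).
#' @return A one-row `data.frame` of class `mesh_quality_report` with columns
#'   `n_nodes`, `n_tets`, `min_volume`, `max_volume`, `n_inverted`,
#'   `n_degenerate`, `total_volume`.
#' @export
validate_mesh <- function(mesh, degenerate_tol = 1e-9) {
  stopifnot(inherits(mesh, "tet_mesh"))
  vols <- tet_volumes(mesh)
  rep <- data.frame(
    n_nodes = nrow(mesh$nodes),
    n_tets = nrow(mesh$tets),
    min_volume = if (length(vols)) min(vols) else NA_real_,
    max_volume = if (length(vols)) max(vols) else NA_real_,
    n_inverted = sum(vols < 0),
    n_degenerate = sum(abs(vols) < degenerate_tol),
    total_volume = sum(vols)
  )
  class(rep) <- c("mesh_quality_report", class(rep))
  rep
}

assert_simulation_mesh <- function(mesh) {
  rep <- validate_mesh(mesh)
  if (rep$n_inverted > 0L || rep$n_degenerate > 0L)
    stopf("mesh rejected: %d inverted and %d degenerate tetrahedra",
          rep$n_inverted, rep$n_degenerate)
  if (is.null(mesh$node_sets$pelvis) || length(mesh$node_sets$pelvis) == 0L)
    stopf("mesh rejected: empty or missing 'pelvis' node set")
  invisible(mesh)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets, %d surface triangles\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$surface_tris)))
  if (length(x$node_sets))
    cat("node sets:",
        paste(sprintf("%s (%d)", names(x$node_sets),
                      vapply(x$node_sets, length, 1L)), collapse = ", "), "\n")
  invisible(x)
}
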