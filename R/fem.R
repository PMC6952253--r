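#' Build a corotational finite-element model
#'
#' Assembles per-element stiffness matrices of linear tetrahedra from the
#' isotropic elasticity tensor, lumps mass as `rho * V_tet / 4` to each of a
#' tetrahedron's nodes, and records the Dirichlet (fixed) node set. Node
#' positions are in mm and forces in N; internally the mm-N-s-tonne unit
#' system is used, so the Young's modulus given in Pa enters the stiffness
#' in MPa (N/mm^2).
#'
#' @param mesh a [tet_mesh()]; rejected if it contains inverted or
#'   degenerate elements.
#' @param material a [material_params()].
#' @param constrained integer node indices held fixed (Dirichlet), or the
#'   name of a node set on `mesh`; defaults to the `"pelvis"` set.
#' @return An object of class `fem_model`.
#' @export
build_fem_model <- function(mesh, material = material_params(),
                            constrained = "pelvis") {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(material, "material_params"))
  rep <- validate_mesh(mesh)
  if (rep$n_inverted > 0L || rep$n_degenerate > 0L)
    stopf("cannot build model: %d inverted, %d degenerate elements",
          rep$n_inverted, rep$n_degenerate)
  if (is.character(constrained)) {
    if (is.null(mesh$node_sets[[constrained]]))
      stopf("mesh has no node set '%s'", constrained)
    constrained <- mesh$node_sets[[constrained]]
  }
  constrained <- sort(unique(as.integer(constrained)))
  n <- nrow(mesh$nodes)
  if (length(constrained) && (min(constrained) < 1L || max(constrained) > n))
    stopf("constrained node index out of range [1, %d]", n)
  if (!length(constrained))
    stopf("the Dirichlet set must be non-empty for a simulation model")

  pre <- fem_precompute_cpp(mesh$nodes, mesh$tets, material$E / 1e6, material$nu)

  vols <- pre$vols
  lumped <- numeric(n)
  m_tet <- material$rho * vols * 1e-9 / 4  # kg per node share
  for (a in 1:4) {
    acc <- tapply(m_tet, mesh$tets[, a], sum)
    ix <- as.integer(names(acc))
    lumped[ix] <- lumped[ix] + as.numeric(acc)
  }

  structure(list(
    mesh = mesh,
    material = material,
    element_stiffness = pre$Ke,   # 12 x 12 x M, N/mm
    dm_inv = pre$DmInv,
    element_volumes = vols,
    lumped_mass = lumped,         # kg
    constrained = constrained,
    rest_positions = mesh$nodes
  ), class = "fem_model")
}

#' @export
print.fem_model <- function(x, ...) {
  cat(sprintf(
    "fem_model: %d nodes, %d tets, %d constrained | E = %g Pa, nu = %g, rho = %g kg/m^3\n",
    nrow(x$mesh$nodes), nrow(x$mesh$tets), length(x$constrained),
    x$material$E, x$material$nu, x$material$rho))
  invisible(x)
}

#' Kinematic state of the deformable model
#'
#' @param model a [build_fem_model()] result.
#' @param u optional N x 3 initial displacements (mm); zeroed on the
#'   constrained nodes.
#' @param v optional N x 3 initial velocities (mm/s).
#' @param t simulation time (s).
#' @return An object of class `fem_state` with fields `u`, `v`, `t`.
#' @export
fem_state <- function(model, u = NULL, v = NULL, t = 0) {
  stopifnot(inherits(model, "fem_model"))
  n <- nrow(model$rest_positions)
  if (is.null(u)) u <- matrix(0, n, 3L)
  if (is.null(v)) v <- matrix(0, n, 3L)
  stopifnot(identical(dim(u), c(n, 3L)) || identical(dim(u), as.integer(c(n, 3L))),
            nrow(v) == n, ncol(v) == 3L)
  u <- as.matrix(u); v <- as.matrix(v)
  u[model$constrained, ] <- 0
  v[model$constrained, ] <- 0
  structure(list(u = u, v = v, t = t), class = "fem_state")
}

#' Rotation factor of the polar decomposition
#'
#' Extracts the rotation `R` of `F = R S` via SVD with determinant
#' correction (`U diag(1, 1, det(U V^T)) V^T`), the corotational frame of an
#' element with deformation gradient `F`.
#'
#' @param F 3 x 3 deformation gradient with `det(F) > 0`.
#' @return 3 x 3 proper rotation matrix.
#' @export
element_rotation <- function(F) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)))
  if (det(F) <= 0)
    stopf("inverted element: det(F) = %.3g <= 0", det(F))
  polar_rotation_cpp(F)
}

#' Corotational internal (elastic) forces
#'
#' Per element, forces are `R K (R^T x - x0)` scattered to the nodes with a
#' negative sign (the restoring force, i.e. the negative elastic gradient).
#' Rigid motions of the whole mesh produce no force.
#'
#' @param model a `fem_model`.
#' @param state a `fem_state`.
#' @return N x 3 matrix of nodal forces (N).
#' @export
internal_forces <- function(model, state) {
  stopifnot(inherits(model, "fem_model"), inherits(state, "fem_state"))
  pos <- model$rest_positions + state$u
  rot <- fem_rotations_cpp(pos, model$rest_positions, model$mesh$tets,
                           model$dm_inv)
  if (rot$inverted > 0)
    stopf("inverted element %d at current positions", rot$inverted)
  fem_forces_cpp(pos, model$rest_positions, model$mesh$tets,
                 model$element_stiffness, rot$R)$forces
}

#' Mechanical energies of a state
#'
#' @param model a `fem_model`.
#' @param state a `fem_state`.
#' @return list with `strain_J` (corotational strain energy) and
#'   `kinetic_J`, both in joules.
#' @export
fem_energies <- function(model, state) {
  pos <- model$rest_positions + state$u
  rot <- fem_rotations_cpp(pos, model$rest_positions, model$mesh$tets,
                           model$dm_inv)
  if (rot$inverted > 0)
    stopf("inverted element %d at current positions", rot$inverted)
  strain <- fem_forces_cpp(pos, model$rest_positions, model$mesh$tets,
                           model$element_stiffness, rot$R)$energy
  kinetic <- 0.5 * sum(model$lumped_mass * 1e-3 * rowSums(state$v^2))
  list(strain_J = strain * 1e-3, kinetic_J = kinetic * 1e-3)
}

#' One implicit backward Euler step
#'
#' Solves the velocity update
#' `(M + dt C + dt^2 K~) dv = dt (f_ext + f_int(x) - C v)` with the
#' corotational tangent `K~ = sum_e R_e K_e R_e^T` frozen at the step start
#' and Rayleigh damping `C = alpha M + beta K~`, using Jacobi-preconditioned
#' conjugate gradients with the Dirichlet constraints enforced by projection
#' (constrained rows of the right-hand side, residual and search direction
#' are zeroed). Then `x <- x + dt (v + dv)`; constrained nodes remain
#' exactly at their rest positions.
#'
#' @param model a `fem_model`.
#' @param state a `fem_state`.
#' @param f_ext N x 3 external nodal forces (N); ignored on constrained
#'   nodes. `NULL` for none.
#' @param dt time step (s); default 1/60, the visual simulation rate.
#' @param ext_stiffness optional per-node isotropic spring stiffness (N/mm)
#'   of external attachments (the needle coupling springs); folded into the
#'   implicit system so stiff couplings cannot destabilise the step. The
#'   springs' forces at the step start belong in `f_ext`.
#' @param ext_damping optional per-node isotropic viscous coefficient
#'   (N s/mm) of external attachments (needle shaft friction), likewise
#'   treated implicitly.
#' @param cg_tol relative residual tolerance of the linear solve.
#' @param cg_maxiter maximum CG iterations.
#' @return The updated `fem_state`, with attributes `iterations`,
#'   `strain_J`, `kinetic_J` attached for logging.
#' @export
step_backward_euler <- function(model, state, f_ext = NULL, dt = 1 / 60,
                                ext_stiffness = NULL, ext_damping = NULL,
                                cg_tol = 1e-8, cg_maxiter = 500L) {
  stopifnot(inherits(model, "fem_model"), inherits(state, "fem_state"), dt > 0)
  n <- nrow(model$rest_positions)
  if (is.null(f_ext)) f_ext <- matrix(0, n, 3L)
  f_ext <- as.matrix(f_ext)
  stopifnot(nrow(f_ext) == n, ncol(f_ext) == 3L)
  if (any(!is.finite(f_ext))) stopf("non-finite external forces")
  f_ext[model$constrained, ] <- 0
  if (is.null(ext_stiffness)) ext_stiffness <- numeric(n)
  if (is.null(ext_damping)) ext_damping <- numeric(n)
  stopifnot(length(ext_stiffness) == n, all(ext_stiffness >= 0),
            length(ext_damping) == n, all(ext_damping >= 0))

  res <- fem_step_cpp(model$rest_positions, state$u, state$v, model$mesh$tets,
                      model$dm_inv, model$element_stiffness,
                      model$lumped_mass * 1e-3, as.integer(model$constrained),
                      f_ext, as.numeric(ext_stiffness), as.numeric(ext_damping),
                      dt, model$material$rayleigh_alpha,
                      model$material$rayleigh_beta, cg_tol, as.integer(cg_maxiter))
  if (!isTRUE(res$ok))
    stopf("inverted element %d during step at t = %.4f s", res$inverted, state$t)
  if (!isTRUE(res$converged))
    stopf("linear solve failed to converge in %d iterations (relative residual %.3g)",
          cg_maxiter, res$relres)

  out <- structure(list(u = res$u, v = res$v, t = state$t + dt),
                   class = "fem_state")
  attr(out, "iterations") <- res$iterations
  attr(out, "strain_J") <- res$strain_energy_mJ * 1e-3
  attr(out, "kinetic_J") <- res$kinetic_energy_mJ * 1e-3
  out
}
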