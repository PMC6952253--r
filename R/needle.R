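#' Rigid-line needle state
#'
#' The needle is an idealised rigid segment: `tip` plus unit direction
#' `dir` pointing tip-ward; the shaft extends `length` mm behind the tip.
#' `phase` tracks the puncture state machine: `free` -> `at_surface` ->
#' `inserted` -> `free` (on retraction).
#'
#' @param tip tip position (mm, world).
#' @param dir unit direction, tip-ward.
#' @param length shaft length (mm).
#' @param tip_velocity tip velocity (mm/s).
#' @param phase one of `"free"`, `"at_surface"`, `"inserted"`.
#' @param membrane_force current capsule resistance (N, along `-dir`).
#' @return An object of class `needle_state`.
#' @export
needle_state <- function(tip, dir, length = 150, tip_velocity = c(0, 0, 0),
                         phase = c("free", "at_surface", "inserted"),
                         membrane_force = 0) {
  phase <- match.arg(phase)
  stopifnot(is_num3(tip), is_num3(dir), is_num3(tip_velocity), length > 0)
  structure(list(tip = as.numeric(tip), dir = normalize(dir),
                 length = as.numeric(length),
                 tip_velocity = as.numeric(tip_velocity), phase = phase,
                 membrane_force = membrane_force),
            class = "needle_state")
}

#' Needle-tissue coupling parameters
#'
#' Force-law constants for the nearest-node coupling, axial friction and
#' capsule puncture. The defaults are in the range reported for biopsy
#' needle insertion and are meant to be tuned per scenario.
#'
#' @param d_thr coupling distance threshold (mm).
#' @param k_perp lateral spring stiffness toward the needle axis (N/mm).
#' @param mu_viscous axial viscous friction (N s/mm).
#' @param f_coulomb_per_node axial Coulomb friction per coupled node (N).
#' @param f_puncture capsule puncture threshold (N).
#' @param k_membrane pre-puncture membrane stiffness (N/mm).
#' @param drop_factor post-puncture force retention, in `[0, 1)`.
#' @return An object of class `coupling_params`.
#' @export
coupling_params <- function(d_thr = 4, k_perp = 0.3, mu_viscous = 0.05,
                            f_coulomb_per_node = 0.02, f_puncture = 1.5,
                            k_membrane = 0.5, drop_factor = 0.3) {
  vals <- c(d_thr, k_perp, mu_viscous, f_coulomb_per_node, f_puncture,
            k_membrane, drop_factor)
  if (any(vals < 0)) stopf("coupling parameters must be >= 0")
  if (drop_factor >= 1) stopf("drop_factor must be < 1")
  structure(list(d_thr = d_thr, k_perp = k_perp, mu_viscous = mu_viscous,
                 f_coulomb_per_node = f_coulomb_per_node,
                 f_puncture = f_puncture, k_membrane = k_membrane,
                 drop_factor = drop_factor),
            class = "coupling_params")
}

#' Nodes within the coupling threshold of the needle shaft
#'
#' Point-to-segment distances against the needle segment (from the tip
#' backwards along `dir` for `length` mm, clamped at both endpoints).
#'
#' @param positions N x 3 current node positions (mm).
#' @param needle a [needle_state()].
#' @param d_thr distance threshold (mm).
#' @return `data.frame` with columns `node` (index, ascending), `distance`
#'   (mm) and `axial` (projection parameter measured from the tail end, in
#'   `[0, length]`).
#' @export
nearest_nodes <- function(positions, needle, d_thr) {
  stopifnot(inherits(needle, "needle_state"), d_thr > 0)
  positions <- as.matrix(positions)
  tail_pt <- needle$tip - needle$length * needle$dir
  rel <- sweep(positions, 2L, tail_pt)
  s <- clamp(as.numeric(rel %*% needle$dir), 0, needle$length)
  closest <- outer(s, needle$dir)
  d2 <- rowSums((rel - closest)^2)
  sel <- which(d2 <= d_thr^2)
  data.frame(node = sel, distance = sqrt(d2[sel]), axial = s[sel])
}

#' Needle-tissue coupling forces
#'
#' In phase `inserted`, each coupled node receives a lateral spring force
#' `k_perp * (closest point on axis - x_i)` pulling it onto the shaft, and
#' the needle feels axial friction
#' `-(mu_viscous * v_rel + f_coulomb_per_node * n * sign(v_rel)) * dir`,
#' where `v_rel` is the axial tip velocity relative to the mean coupled
#' tissue velocity. The tissue-side friction reaction is distributed
#' equally among coupled nodes, so total tissue force plus needle reaction
#' is exactly zero.
#'
#' @param model a `fem_model`.
#' @param state a `fem_state`.
#' @param needle a [needle_state()]; must be in phase `inserted`.
#' @param params a [coupling_params()].
#' @return list of class `coupling_result`: `coupled_nodes`, `node_forces`
#'   (k x 3, N, tissue side), `needle_force` (3-vector, N, reaction on the
#'   handle), `phase_after`.
#' @export
coupling_forces <- function(model, state, needle, params) {
  stopifnot(inherits(model, "fem_model"), inherits(state, "fem_state"),
            inherits(needle, "needle_state"), inherits(params, "coupling_params"))
  if (needle$phase != "inserted")
    stopf("coupling_forces requires phase 'inserted', got '%s'", needle$phase)

  pos <- model$rest_positions + state$u
  nn <- nearest_nodes(pos, needle, params$d_thr)
  k <- nrow(nn)
  if (k == 0L) {
    return(structure(list(coupled_nodes = integer(0),
                          node_forces = matrix(0, 0L, 3L),
                          needle_force = c(0, 0, 0), phase_after = needle$phase),
                     class = "coupling_result"))
  }
  tail_pt <- needle$tip - needle$length * needle$dir
  closest <- sweep(outer(nn$axial, needle$dir), 2L, tail_pt, "+")
  lateral <- params$k_perp * (closest - pos[nn$node, , drop = FALSE])

  v_tissue <- colMeans(state$v[nn$node, , drop = FALSE])
  v_rel <- sum((needle$tip_velocity - v_tissue) * needle$dir)
  fric_mag <- params$mu_viscous * v_rel +
    params$f_coulomb_per_node * k * sign(v_rel)
  friction <- -fric_mag * needle$dir  # on the needle

  node_forces <- lateral + matrix(-friction / k, k, 3L, byrow = TRUE)
  needle_force <- -colSums(lateral) + friction

  structure(list(coupled_nodes = nn$node, node_forces = node_forces,
                 needle_force = needle_force, phase_after = needle$phase),
            class = "coupling_result")
}

#' Signed tip-to-surface gap along the needle direction
#'
#' Ray-casts the needle line against the mesh boundary triangles
#' (Moller-Trumbore). Positive: distance from the tip to the first surface
#' crossing ahead along `dir`; negative: the tip has penetrated, magnitude
#' is the axial distance back to the entry crossing; `Inf` when the line
#' misses the surface entirely.
#'
#' @param mesh a [tet_mesh()] (rest configuration).
#' @param needle a [needle_state()].
#' @return scalar gap (mm).
#' @export
surface_gap <- function(mesh, needle) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(needle, "needle_state"))
  tri <- mesh$surface_tris
  if (nrow(tri) == 0L) return(Inf)
  a <- mesh$nodes[tri[, 1L], , drop = FALSE]
  e1 <- mesh$nodes[tri[, 2L], , drop = FALSE] - a
  e2 <- mesh$nodes[tri[, 3L], , drop = FALSE] - a
  d <- needle$dir
  # p = d x e2
  p <- cbind(d[2L] * e2[, 3L] - d[3L] * e2[, 2L],
             d[3L] * e2[, 1L] - d[1L] * e2[, 3L],
             d[1L] * e2[, 2L] - d[2L] * e2[, 1L])
  det <- rowSums(e1 * p)
  ok <- abs(det) > 1e-12
  tv <- sweep(-a, 2L, needle$tip, "+")  # tip - a
  uu <- rowSums(tv * p) / det
  q <- cbind(tv[, 2L] * e1[, 3L] - tv[, 3L] * e1[, 2L],
             tv[, 3L] * e1[, 1L] - tv[, 1L] * e1[, 3L],
             tv[, 1L] * e1[, 2L] - tv[, 2L] * e1[, 1L])
  vv <- (q[, 1L] * d[1L] + q[, 2L] * d[2L] + q[, 3L] * d[3L]) / det
  tt <- rowSums(e2 * q) / det
  hit <- ok & uu >= -1e-12 & vv >= -1e-12 & (uu + vv) <= 1 + 1e-12
  ts <- tt[hit]
  if (!length(ts)) return(Inf)
  # collapse coincident crossings (ray through a shared vertex or edge hits
  # several triangles at the same t) so the parity test stays sound
  ts <- sort(ts)
  ts <- ts[c(TRUE, diff(ts) > 1e-7)]
  ahead <- ts[ts > 1e-9]
  behind <- ts[ts <= 1e-9]
  inside <- length(ahead) %% 2L == 1L
  if (inside) {
    if (length(behind)) max(behind) else -min(ahead)
  } else {
    if (length(ahead)) min(ahead) else Inf
  }
}

#' Capsule puncture state machine
#'
#' While the tip presses on the surface (phase `at_surface`) a membrane
#' force `k_membrane * |gap|` resists advance; when it reaches
#' `f_puncture` the capsule breaks (phase `inserted`) and the resistance
#' drops to `drop_factor * f_puncture`; retracting the tip above the
#' surface returns the needle to `free`.
#'
#' @param needle a [needle_state()].
#' @param surface_gap signed tip-to-surface distance along `dir` (mm);
#'   negative = penetrated (see [surface_gap()]).
#' @param axial_contact_force current axial contact force (N); recorded for
#'   force-profile logging, not used by the transitions.
#' @param params a [coupling_params()].
#' @return The updated `needle_state`; `$membrane_force` holds the
#'   resisting force magnitude (N, applied along `-dir`).
#' @export
puncture_update <- function(needle, surface_gap, axial_contact_force = 0,
                            params = coupling_params()) {
  stopifnot(inherits(needle, "needle_state"), inherits(params, "coupling_params"))
  gap <- surface_gap
  if (needle$phase %in% c("free", "at_surface")) {
    if (is.finite(gap) && gap <= 0) {
      f_mem <- params$k_membrane * (-gap)
      if (f_mem >= params$f_puncture) {
        needle$phase <- "inserted"
        needle$membrane_force <- params$drop_factor * params$f_puncture
      } else {
        needle$phase <- "at_surface"
        needle$membrane_force <- f_mem
      }
    } else {
      needle$phase <- "free"
      needle$membrane_force <- 0
    }
  } else { # inserted
    if (!is.finite(gap) || gap > 0) {
      needle$phase <- "free"
      needle$membrane_force <- 0
    } else {
      needle$membrane_force <- params$drop_factor * params$f_puncture
    }
  }
  needle
}

#' Total haptic reaction force
#'
#' Sum of the coupling reaction on the needle handle and the membrane
#' resistance applied along `-dir`. Zero for a free needle with no
#' contacts.
#'
#' @param coupling a [coupling_forces()] result, or `NULL` when not
#'   inserted.
#' @param needle a [needle_state()].
#' @param membrane_force membrane force magnitude (N); defaults to the one
#'   recorded on `needle`.
#' @return 3-vector (N).
#' @export
haptic_force <- function(coupling, needle, membrane_force = needle$membrane_force) {
  stopifnot(inherits(needle, "needle_state"))
  f <- if (is.null(coupling)) c(0, 0, 0) else coupling$needle_force
  if (any(!is.finite(f)) || !is.finite(membrane_force))
    stopf("non-finite force input")
  f - membrane_force * needle$dir
}
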