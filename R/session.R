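#' Default session configuration
#'
#' Nested parameter list driving [run_session()]: phantom spec, trajectory,
#' material, solver, needle coupling, view, overlay and haptics groups.
#' Any subset can be overridden by the `config` argument of
#' [run_session()] or by a YAML file via [load_session_config()]; values
#' merge over these defaults.
#'
#' @param seed integer seed for all stochastic generation.
#' @return nested named list.
#' @export
default_session_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    duration_s = 10,
    phantom = list(dims = c(128L, 128L, 96L), spacing = c(0.8, 0.8, 0.8),
                   semi_axes = c(45, 25, 25), sigma_s = 0.5),
    material = list(E_pa = 1e5, nu = 0.3, rho = 1050,
                    rayleigh_alpha = 1.0, rayleigh_beta = 0.01),
    solver = list(dt = 1 / 60, cg_tol = 1e-8, cg_maxiter = 500L),
    needle = list(length_mm = 150,
                  coupling = list(d_thr_mm = 4, k_perp = 0.3, mu_viscous = 0.05,
                                  f_coulomb = 0.02, f_puncture = 1.5,
                                  k_membrane = 0.5, drop_factor = 0.3)),
    view = list(width_px = 128L, height_px = 96L, pixel_spacing_mm = 1,
                slab_halfthickness_mm = 2),
    overlay = list(amplitude = 200, sigma_mm = 0.6),
    haptics = list(rate_hz = 1000, smoothing_window = 1L),
    # trajectory: NULL = the canonical scan/aim/insert/retract script; a
    # trajectory_spec object; or a list with $keyframes of
    # (t, probe_centre, tip, dir) as read from YAML
    trajectory = NULL,
    target_mm = NULL  # default: 20 mm inside the capsule on the insertion axis
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.object(override[[nm]]) && !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a session configuration from YAML
#'
#' Keys mirror [default_session_config()]; missing keys take the defaults.
#'
#' @param path YAML file.
#' @param seed seed used where the file does not set one.
#' @return nested named list.
#' @export
load_session_config <- function(path, seed = 1L) {
  merge_config(default_session_config(seed), yaml::read_yaml(path))
}

#' Run a scripted biopsy session
#'
#' The full simulation loop, one deterministic pass per time step: scripted
#' poses -> puncture state machine -> nearest-node coupling forces -> FEM
#' backward Euler step (needle forces as external load) -> haptic force log
#' -> reslice -> deformation warp -> needle echo overlay -> frame. After
#' the loop the simulation force log is resampled to the haptic rate
#' through the zeroth-order-hold channel.
#'
#' @param config overrides merged over [default_session_config()].
#' @param out_dir output directory; when given, writes
#'   `frames/frame_%06d.png`, `forces_sim.csv`, `forces_haptic.csv`,
#'   `metrics.json`, `effective_config.yaml` and `session.log`.
#' @param keep_frames keep every frame's pixel matrix in the result (for
#'   programmatic inspection; frames are always rendered either way).
#' @param verbose print per-second progress.
#' @return An object of class `session_result`: `metrics` (list),
#'   `forces_sim` and `forces_haptic` (data.frames), `config`, and
#'   optionally `frames`.
#' @export
run_session <- function(config = list(), out_dir = NULL, keep_frames = FALSE,
                        verbose = FALSE) {
  cfg <- merge_config(default_session_config(), config)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }

  say("building phantom (seed %d)", cfg$seed)
  pspec <- phantom_spec(dims = cfg$phantom$dims, spacing = cfg$phantom$spacing,
                        semi_axes = cfg$phantom$semi_axes,
                        sigma_s = cfg$phantom$sigma_s,
                        mesh_spacing = cfg$phantom$mesh_spacing, seed = cfg$seed)
  ph <- generate_phantom(pspec)
  assert_simulation_mesh(ph$mesh)

  material <- material_params(E = cfg$material$E_pa, nu = cfg$material$nu,
                              rho = cfg$material$rho,
                              rayleigh_alpha = cfg$material$rayleigh_alpha,
                              rayleigh_beta = cfg$material$rayleigh_beta)
  model <- build_fem_model(ph$mesh, material, constrained = "pelvis")
  state <- fem_state(model)

  traj <- cfg$trajectory
  if (is.null(traj)) {
    traj <- canonical_insertion_trajectory(pspec, view = cfg$view)
  } else if (!inherits(traj, "trajectory_spec")) {
    # plain-list form (e.g. from YAML): keyframes of t, probe_centre, tip, dir
    kfs <- lapply(traj$keyframes, function(k) list(
      t = k$t,
      probe = probe_pose(as.numeric(k$probe_centre), diag(3),
                         cfg$view$width_px, cfg$view$height_px,
                         cfg$view$pixel_spacing_mm,
                         cfg$view$slab_halfthickness_mm),
      tip = as.numeric(k$tip), dir = as.numeric(k$dir)))
    traj <- trajectory_spec(kfs, interpolation = traj$interpolation %||% "linear",
                            duration = traj$duration)
  }
  cpar <- coupling_params(d_thr = cfg$needle$coupling$d_thr_mm,
                          k_perp = cfg$needle$coupling$k_perp,
                          mu_viscous = cfg$needle$coupling$mu_viscous,
                          f_coulomb_per_node = cfg$needle$coupling$f_coulomb,
                          f_puncture = cfg$needle$coupling$f_puncture,
                          k_membrane = cfg$needle$coupling$k_membrane,
                          drop_factor = cfg$needle$coupling$drop_factor)
  target <- cfg$target_mm
  if (is.null(target))
    target <- pspec$centre + c(pspec$semi_axes[1L] - 20, 0, 0)

  dt <- cfg$solver$dt
  n_steps <- floor(cfg$duration_s / dt) + 1L  # includes t = 0
  frames_dir <- NULL
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "frames"), recursive = TRUE, showWarnings = FALSE)
    frames_dir <- file.path(out_dir, "frames")
  }

  phase <- "free"
  punctures <- 0L
  path_len <- 0
  min_target_dist <- Inf
  prev_tip <- NULL
  frames <- if (keep_frames) vector("list", n_steps) else NULL
  log <- data.frame(t = numeric(n_steps), phase = character(n_steps),
                    n_coupled = integer(n_steps), fx = 0, fy = 0, fz = 0,
                    f_mag = 0, strain_energy_J = 0, kinetic_energy_J = 0,
                    max_constraint_violation_mm = 0,
                    stringsAsFactors = FALSE)
  step_times <- numeric(n_steps)

  for (k in seq_len(n_steps)) {
    t0 <- proc.time()[[3L]]
    t <- (k - 1L) * dt
    p <- poses_at(traj, min(t, traj$duration))
    needle <- p$needle
    needle$length <- cfg$needle$length_mm
    needle$phase <- phase

    gap <- surface_gap(ph$mesh, needle)
    needle <- puncture_update(needle, gap, params = cpar)
    if (phase != "inserted" && needle$phase == "inserted")
      punctures <- punctures + 1L
    phase <- needle$phase

    coupling <- NULL
    f_ext <- NULL
    ext_k <- NULL
    ext_c <- NULL
    if (phase == "inserted") {
      coupling <- coupling_forces(model, state, needle, cpar)
      nc <- length(coupling$coupled_nodes)
      if (nc) {
        f_ext <- matrix(0, nrow(model$rest_positions), 3L)
        f_ext[coupling$coupled_nodes, ] <- coupling$node_forces
        # the coupling springs and shaft friction are stiff relative to the
        # parenchyma: fold their stiffness/viscosity into the implicit solve
        ext_k <- numeric(nrow(model$rest_positions))
        ext_k[coupling$coupled_nodes] <- cpar$k_perp
        ext_c <- numeric(nrow(model$rest_positions))
        ext_c[coupling$coupled_nodes] <- cpar$mu_viscous / nc
      }
    }

    state <- step_backward_euler(model, state, f_ext = f_ext, dt = dt,
                                 ext_stiffness = ext_k, ext_damping = ext_c,
                                 cg_tol = cfg$solver$cg_tol,
                                 cg_maxiter = cfg$solver$cg_maxiter)

    fh <- haptic_force(coupling, needle)

    img <- warp_with_deformation(ph$volume, p$probe, ph$mesh, state$u, t = t)
    img <- needle_overlay(img, p$probe, needle,
                          echo = list(amplitude = cfg$overlay$amplitude,
                                      sigma_mm = cfg$overlay$sigma_mm))
    if (!is.null(frames_dir))
      write_frame_png(img, file.path(frames_dir, sprintf("frame_%06d.png", k - 1L)))
    if (keep_frames) frames[[k]] <- img$pixels

    if (!is.null(prev_tip)) path_len <- path_len + sqrt(sum((needle$tip - prev_tip)^2))
    prev_tip <- needle$tip
    min_target_dist <- min(min_target_dist, sqrt(sum((needle$tip - target)^2)))

    log$t[k] <- t
    log$phase[k] <- phase
    log$n_coupled[k] <- if (is.null(coupling)) 0L else length(coupling$coupled_nodes)
    log$fx[k] <- fh[1L]; log$fy[k] <- fh[2L]; log$fz[k] <- fh[3L]
    log$f_mag[k] <- sqrt(sum(fh^2))
    log$strain_energy_J[k] <- attr(state, "strain_J")
    log$kinetic_energy_J[k] <- attr(state, "kinetic_J")
    log$max_constraint_violation_mm[k] <-
      if (length(model$constrained)) max(abs(state$u[model$constrained, ])) else 0
    step_times[k] <- proc.time()[[3L]] - t0
    if (verbose && k %% 60L == 1L)
      say("t = %5.2f s  phase = %-10s |f| = %6.3f N", t, phase, log$f_mag[k])
  }

  chan <- force_channel(log$t, as.matrix(log[, c("fx", "fy", "fz")]),
                        haptic_rate = cfg$haptics$rate_hz,
                        smoothing_window = cfg$haptics$smoothing_window)
  haptic_log <- resample_haptic(chan)

  metrics <- list(
    final_tip_target_distance_mm = sqrt(sum((prev_tip - target)^2)),
    min_tip_target_distance_mm = min_target_dist,
    peak_haptic_force_N = max(log$f_mag),
    needle_path_length_mm = path_len,
    punctures = punctures,
    frames = n_steps,
    step_time_mean_s = mean(step_times),
    step_time_max_s = max(step_times)
  )
  say("done: %d frames, %d puncture(s), peak force %.3f N", n_steps, punctures,
      metrics$peak_haptic_force_N)

  if (!is.null(out_dir)) {
    write.csv(log, file.path(out_dir, "forces_sim.csv"), row.names = FALSE)
    write.csv(haptic_log, file.path(out_dir, "forces_haptic.csv"), row.names = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(cfg, file.path(out_dir, "effective_config.yaml"))
    writeLines(log_lines, file.path(out_dir, "session.log"))
  }

  structure(list(metrics = metrics, forces_sim = log, forces_haptic = haptic_log,
                 config = cfg, frames = frames),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0(
    "session_result: %d frames, %d puncture(s)\n",
    "  peak haptic force     %.3f N\n",
    "  needle path length    %.1f mm\n",
    "  final tip-to-target   %.2f mm\n"),
    m$frames, m$punctures, m$peak_haptic_force_N, m$needle_path_length_mm,
    m$final_tip_target_distance_mm))
  invisible(x)
}
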