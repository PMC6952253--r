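test_that("a trajectory that never approaches the phantom yields a null session", {
  cfg <- small_session_config(duration_s = 1)
  ctr <- c(32, 32, 24)
  cfg$trajectory <- far_trajectory(ctr, cfg$view, duration = 1)
  res <- run_session(cfg, keep_frames = TRUE)

  expect_equal(res$metrics$peak_haptic_force_N, 0)
  expect_equal(res$metrics$punctures, 0L)
  expect_equal(res$metrics$frames, floor(1 / (1 / 60)) + 1L)
  expect_equal(nrow(res$forces_sim), res$metrics$frames)
  expect_true(all(res$forces_sim$f_mag == 0))
  expect_true(all(res$forces_sim$phase == "free"))
  expect_lte(max(res$forces_sim$max_constraint_violation_mm), 1e-10)

  # every frame equals the plain reslice at the (static) probe pose
  ph <- generate_phantom(phantom_spec(dims = cfg$phantom$dims,
                                      spacing = cfg$phantom$spacing,
                                      semi_axes = cfg$phantom$semi_axes,
                                      sigma_s = cfg$phantom$sigma_s,
                                      mesh_spacing = cfg$phantom$mesh_spacing,
                                      seed = cfg$seed %||% 1L))
  pp <- probe_pose(ctr, diag(3), cfg$view$width_px, cfg$view$height_px,
                   cfg$view$pixel_spacing_mm, cfg$view$slab_halfthickness_mm)
  ref <- reslice(ph$volume, pp)
  expect_identical(res$frames[[1]], ref$pixels)
  expect_identical(res$frames[[length(res$frames)]], ref$pixels)
})

test_that("an insertion session punctures once with the expected force ramp", {
  cfg <- small_session_config(duration_s = 2.5)
  ctr <- c(32, 32, 24)
  cfg$trajectory <- insertion_trajectory(ctr, a = 20, cfg$view,
                                         duration = 2.5, speed = 10)
  res <- run_session(cfg, keep_frames = FALSE)
  log <- res$forces_sim

  expect_equal(res$metrics$punctures, 1L)
  first_ins <- match("inserted", log$phase)
  expect_false(is.na(first_ins))
  pre <- log$f_mag[seq_len(first_ins - 1L)]
  # peak force before puncture reaches f_puncture within one ramp increment
  ramp <- 0.5 * 10 * (1 / 60)  # k_membrane * speed * dt
  expect_gte(max(pre), 1.5 - ramp - 1e-12)
  expect_lte(max(pre), 1.5 + ramp + 1e-12)
  expect_gt(sum(log$phase == "at_surface"), 0)
  expect_true(all(is.finite(log$f_mag)))
  expect_lt(res$metrics$peak_haptic_force_N, 20)
  expect_lte(max(log$max_constraint_violation_mm), 1e-10)

  # haptic resampling covers the session span at the configured rate
  expect_equal(nrow(res$forces_haptic),
               floor((max(log$t) - min(log$t)) * 1000) + 1L)
})

test_that("sessions are deterministic and write the declared outputs", {
  cfg <- small_session_config(duration_s = 0.5)
  ctr <- c(32, 32, 24)
  cfg$trajectory <- insertion_trajectory(ctr, a = 20, cfg$view,
                                         duration = 0.5, speed = 30)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_session(cfg, out_dir = d1)
  r2 <- run_session(cfg, out_dir = d2)

  expect_identical(r1$forces_sim, r2$forces_sim)
  expect_identical(r1$forces_haptic, r2$forces_haptic)
  f1 <- list.files(file.path(d1, "frames"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "frames"), full.names = TRUE)
  expect_equal(length(f1), r1$metrics$frames)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_true(all(file.exists(file.path(d1, c("forces_sim.csv", "forces_haptic.csv",
                                              "metrics.json", "effective_config.yaml",
                                              "session.log")))))
  m <- jsonlite::read_json(file.path(d1, "metrics.json"))
  expect_equal(m$punctures, r1$metrics$punctures)
})

test_that("the shipped canonical session config parses and matches the built-in script", {
  cfgf <- system.file("extdata", "session_canonical.yaml", package = "kbsim")
  cfg <- load_session_config(cfgf)
  expect_equal(cfg$duration_s, 10)
  expect_equal(cfg$needle$coupling$f_puncture, 1.5)
  expect_length(cfg$trajectory$keyframes, 5L)
  # the YAML keyframes reproduce the built-in canonical trajectory
  builtin <- canonical_insertion_trajectory(phantom_spec())
  kf <- cfg$trajectory$keyframes
  for (i in seq_along(kf)) {
    expect_equal(kf[[i]]$t, builtin$keyframes[[i]]$t)
    expect_equal(as.numeric(kf[[i]]$tip), builtin$keyframes[[i]]$tip)
    expect_equal(as.numeric(kf[[i]]$probe_centre),
                 builtin$keyframes[[i]]$probe$centre)
  }
})

test_that("the CLI drives mesh, phantom and simulation entry points", {
  td <- withr::local_tempdir()
  out <- file.path(td, "ell.vtk")
  expect_output(kbsim_cli(c("mesh", "make-ellipsoid", "--semi-axes",
                            "12", "8", "8", "--spacing", "4", "--out", out)),
                "wrote")
  expect_output(kbsim_cli(c("mesh", "validate", out)), "n_tets")

  cfgf <- file.path(td, "sess.yaml")
  yaml::write_yaml(list(
    duration_s = 0.1,
    phantom = list(dims = c(48L, 48L, 32L), spacing = c(1, 1, 1),
                   semi_axes = c(14, 9, 9), mesh_spacing = 5),
    view = list(width_px = 32L, height_px = 24L, pixel_spacing_mm = 1.5,
                slab_halfthickness_mm = 2),
    trajectory = list(
      duration = 0.1, interpolation = "linear",
      keyframes = list(
        list(t = 0, probe_centre = c(24, 24, 16), tip = c(400, 0, 0),
             dir = c(-1, 0, 0)),
        list(t = 0.1, probe_centre = c(24, 24, 16), tip = c(400, 0, 0),
             dir = c(-1, 0, 0))))), cfgf)
  outd <- file.path(td, "run")
  expect_output(kbsim_cli(c("simulate", "--config", cfgf, "--out", outd,
                            "--seed", "3")), "session_result")
  expect_true(file.exists(file.path(outd, "forces_sim.csv")))
  expect_equal(length(list.files(file.path(outd, "frames"))), 7L)
})
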