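test_that("force streams wrap the forward reaction in instrument noise", {
  sol <- small_solution()
  # noiseless stream equals the forward reaction curve at the ramp samples
  s0 <- generate_force_stream(sol, noise_spec(force_sd_n = 0), seed = 1)
  on_curve <- s0$delta_mm %in% sol$history$delta_mm & s0$delta_mm > 0
  expect_true(any(on_curve))
  for (i in head(which(on_curve), 3)) {
    expect_equal(s0$force_n[i], reaction_at(sol, s0$delta_mm[i]),
                 tolerance = 1e-9)
  }
  # ramp follows the 5 mm/s feed rate after the pre-contact prefix
  ramp <- s0[s0$delta_mm > 0 & s0$delta_mm < max(s0$delta_mm), ]
  expect_equal(diff(ramp$delta_mm) / diff(ramp$t_s),
               rep(5, nrow(ramp) - 1), tolerance = 1e-9)
  # leading prefix has exactly zero force (exercises record cleaning)
  expect_true(all(s0$force_n[s0$t_s < 0.5] == 0))
  # seed determinism
  n <- noise_spec(force_sd_n = 0.4, seed = 9)
  expect_identical(generate_force_stream(sol, n), generate_force_stream(sol, n))
  expect_false(identical(generate_force_stream(sol, n, seed = 10),
                         generate_force_stream(sol, n, seed = 11)))
})

test_that("ToF rendering and inversion close the loop", {
  geom <- tof_sensor_geometry()
  noise0 <- noise_spec(tof_rmse_mm = 0)
  ref <- render_tof_frames(function(x) rep(0, length(x)), geom, noise0)
  # planted reference cubic profile: row-5 reconstruction within ray-cast
  # tolerance on the cubic's valid range
  msd <- as_mean_surface("R3", 25)
  f <- compose_full_profile(msd)
  fr <- render_tof_frames(f, geom, noise0)
  pts <- to_transverse_points(fr, geom, ref)
  sel <- abs(pts$x_mm) >= 10 & abs(pts$x_mm) <= 60
  expect_gt(sum(sel), 4)
  expect_lt(max(abs(pts$z_mm[sel] - f(abs(pts$x_mm[sel])))), 0.1)
  # same seed gives identical frames
  n <- noise_spec(seed = 4)
  expect_identical(render_tof_frames(f, geom, n), render_tof_frames(f, geom, n))
})

test_that("noisy reconstruction stays within the sensor error envelope", {
  geom <- tof_sensor_geometry()
  noise <- noise_spec()  # rmse 0.805 mm clipped at +-1.6 mm
  ref <- render_tof_frames(function(x) rep(0, length(x)),
                           noise = noise_spec(tof_rmse_mm = 0))
  msd <- as_mean_surface("R3", 25)
  f <- compose_full_profile(msd)
  frames <- render_tof_frames(f, geom, noise, seed = 21,
                              times_s = seq(0, by = 1 / 15, length.out = 100))
  errs <- c()
  for (t in unique(frames$t_s)) {
    pts <- to_transverse_points(frames[frames$t_s == t, ], geom, ref)
    errs <- c(errs, pts$z_mm - f(abs(pts$x_mm)))
  }
  expect_lt(sqrt(mean(errs^2)), 1.0)
  # clipped noise cannot exceed the bound by more than the ray geometry
  # stretches it; check the raw distance perturbation instead
  clean <- render_tof_frames(f, geom, noise_spec(tof_rmse_mm = 0))
  merged <- dplyr::inner_join(
    frames[frames$t_s == 0, c("side", "row", "col", "distance_mm")],
    clean[, c("side", "row", "col", "distance_mm")],
    by = c("side", "row", "col"))
  expect_lte(max(abs(merged$distance_mm.x - merged$distance_mm.y)), 1.6 + 1e-9)
})

test_that("synthetic sEMG closes with the envelope pipeline", {
  noise <- noise_spec(seed = 31)
  # 0% activity: envelope sits at the baseline amplitude
  quiet <- generate_semg(0, noise)
  env0 <- rms_envelope(filter_semg(quiet))
  expect_equal(mean(env0$rms_uv), noise$semg_baseline_uv, tolerance = 1.5)
  # constant 33% profile is recovered by MVC normalization within 3 points
  mvc <- generate_semg(100, noise, seed = 32)
  meas <- generate_semg(33, noise, seed = 33)
  act <- normalize_mvc(rms_envelope(filter_semg(meas)),
                       rms_envelope(filter_semg(mvc)),
                       rms_envelope(filter_semg(quiet)))
  expect_equal(act$activity_pct, 33, tolerance = 3)
  # determinism
  expect_identical(generate_semg(20, noise), generate_semg(20, noise))
})

test_that("experiment suites carry their ground truth in the manifest", {
  dir <- withr::local_tempdir()
  suite <- build_experiment_suite(
    list(ogden_params(8, 15)), delta_max_mm = 8,
    noise = noise_spec(seed = 5), dir = dir, N = 1L, n_steps = 4L)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man[[1]]$c_kpa, 8)
  expect_equal(man[[1]]$m, 15)
  expect_equal(man[[1]]$delta_max_mm, 8)
  expect_true(file.exists(file.path(dir, "exp01_force.csv")))
  # regenerating with the same seed yields byte-identical fixtures
  dir2 <- withr::local_tempdir()
  build_experiment_suite(list(ogden_params(8, 15)), delta_max_mm = 8,
                         noise = noise_spec(seed = 5), dir = dir2,
                         N = 1L, n_steps = 4L)
  for (fn in list.files(dir)) {
    expect_identical(readLines(file.path(dir, fn)),
                     readLines(file.path(dir2, fn)),
                     label = fn)
  }
})

test_that("the zero-noise pipeline recovers planted parameters end to end", {
  p_true <- ogden_params(10, 20)
  truth <- truth_solution()
  noise0 <- noise_spec(force_sd_n = 0, tof_rmse_mm = 0)
  geom <- tof_sensor_geometry()

  # force branch: stream -> clean -> polynomial fit
  stream <- generate_force_stream(truth, noise0, seed = 2)
  fit <- fit_force_displacement(clean_record(stream, contact_threshold_n = 1e-9))

  # surface branch: rendered frames -> transverse points -> side fits ->
  # region-mean profiles at the four depth stations
  ref_frames <- render_tof_frames(function(x) rep(0, length(x)), geom, noise0)
  windows <- list()
  d4 <- truth$delta_i_mm
  for (i in seq_along(d4)) {
    prof <- surface_profile(truth, d4[i])
    ufun <- splinefun(prof$r_mm, prof$u_mm, method = "monoH.FC")
    surface_fun <- function(x) {
      tip <- indenter_tip_profile(x, d4[i])
      u <- ufun(x)
      ifelse(!is.na(tip) & tip < u, tip, u)
    }
    fr <- render_tof_frames(surface_fun, geom, noise0)
    pts <- to_transverse_points(fr, geom, ref_frames)
    fits <- list(side_profile_fit(pts, d4[i], "right"),
                 side_profile_fit(pts, d4[i], "left"))
    windows[[i]] <- mean_surface_displacement(fits, d4[i], force_fit = fit)
  }
  ref <- structure(
    list(region = "SYN", force_fit = fit, surfaces = windows,
         delta_i_mm = d4, delta_max_star_mm = max(d4),
         f_star_n = vapply(windows, `[[`, numeric(1), "f_star_n"),
         delta_trim_mm = 0.3, eta = 0.5),
    class = "reference_set")

  gs <- grid_search(ref, c_kpa = c(7, 10, 13), m = c(14, 20, 26),
                    N = 1, n_steps = 4)
  expect_equal(gs$p_res$c_kpa, p_true$c_kpa)
  expect_equal(gs$p_res$m, p_true$m)
})
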