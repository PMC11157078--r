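# frame helper: constant-distance frames for both sensors
flat_frames <- function(times = 0, dist = 40) {
  tidyr::expand_grid(side = c("left", "right"), t_s = times,
                     row = 1:8, col = 1:8) |>
    dplyr::mutate(distance_mm = dist)
}

test_that("frame preprocessing smooths spatially and resamples in time", {
  # constant frames are unchanged
  fr <- flat_frames(times = seq(0, 1, by = 1 / 15))
  out <- preprocess_frames(fr)
  expect_true(all(abs(out$distance_mm - 40) < 1e-12))
  # resampling contract: uniform 0.1 s grid
  expect_equal(sort(unique(out$t_s)), seq(0, 1, by = 0.1), tolerance = 1e-9)
  # single-zone step equals the brute-force window mean
  fr2 <- flat_frames(times = 0)
  fr2$distance_mm[fr2$side == "right" & fr2$row == 5 & fr2$col == 4] <- 50
  out2 <- preprocess_frames(fr2)
  got <- out2$distance_mm[out2$side == "right" & out2$row == 5]
  brute <- vapply(1:8, function(i) {
    w <- max(1, i - 2):min(8, i + 2)
    mean(ifelse(w == 4, 50, 40))
  }, numeric(1))
  expect_equal(got[order(out2$col[out2$side == "right" & out2$row == 5])],
               brute, tolerance = 1e-12)
  # long gaps are refused
  fr3 <- flat_frames(times = c(0, 2.5))
  expect_error(preprocess_frames(fr3), "gap")
})

test_that("transverse points invert the shared sensor geometry", {
  geom <- tof_sensor_geometry()
  noise0 <- noise_spec(tof_rmse_mm = 0)
  ref <- render_tof_frames(function(x) rep(0, length(x)), geom, noise0)
  # deformed frame identical to reference: z = 0 everywhere
  pts0 <- to_transverse_points(ref, geom, ref)
  expect_lt(max(abs(pts0$z_mm)), 1e-6)
  expect_true(all(diff(pts0$x_mm[pts0$side == "right"]) > 0))
  # plane 5 mm below the reference: z = -5 within the sensor error bound
  plane <- render_tof_frames(function(x) rep(-5, length(x)), geom, noise0)
  pts5 <- to_transverse_points(plane, geom, ref)
  expect_lt(max(abs(pts5$z_mm + 5)), 0.1)
  # hemispherical dimple: recovered within the stated +-1.6 mm bound
  dimple <- function(x) ifelse(x < 30, -8 * sqrt(pmax(1 - (x / 30)^2, 0)), 0)
  fr <- render_tof_frames(dimple, geom, noise0)
  pts <- to_transverse_points(fr, geom, ref)
  expect_lt(max(abs(pts$z_mm - dimple(abs(pts$x_mm)))), 1.6)
  expect_error(to_transverse_points(fr, geom, NULL), "reference")
})

test_that("side profile fit recovers an exact cubic with the analytic penalty", {
  # cubic through z=0 at x=50 with plausible dimple shape on one side
  cf <- c(-6.175e-05, 4.191e-03, 2.418e-01, -16.31)
  root <- uniroot(function(x) poly_eval(cf, x), c(50, 65))$root
  xs <- seq(10, 45, by = 2.5)
  pts <- dplyr::bind_rows(
    tibble::tibble(side = "right", x_mm = xs, z_mm = poly_eval(cf, xs)),
    tibble::tibble(side = "left", x_mm = -xs, z_mm = poly_eval(cf, xs)))
  fit <- side_profile_fit(pts, delta_i_mm = 25, side = "right")
  expect_lt(fit$rmse, 0.2)
  expect_equal(fit$x_xmax_mm, root, tolerance = 1)
  # zero-RMSE candidate has the analytic penalty Theta = 0.75 * x_xmax / r_C
  expect_equal(fit$theta, fit$rmse + 0.75 * fit$x_xmax_mm / 110,
               tolerance = 1e-12)
  expect_false(fit$penalized)
  # penalty ordering: for equal RMSE a rooted fit beats an unrooted one
  expect_lt(0.75 * 110 / 110, 10)
})

test_that("penalty increases strictly with the plane intersection", {
  q <- function(xxmax) 0.75 * xxmax / 110
  xx <- seq(20, 110, by = 10)
  expect_true(all(diff(q(xx)) > 0))
})

test_that("mean surface displacement reproduces the printed reference rows", {
  # single symmetric pair of identical cubics collapses to that cubic
  cf <- c(-6.175e-05, 4.191e-03, 2.418e-01, -16.31)
  xs <- seq(10, 45, by = 2.5)
  pts <- dplyr::bind_rows(
    tibble::tibble(side = "right", x_mm = xs, z_mm = poly_eval(cf, xs)),
    tibble::tibble(side = "left", x_mm = -xs, z_mm = poly_eval(cf, xs)))
  fits <- list(side_profile_fit(pts, 25, "right"),
               side_profile_fit(pts, 25, "left"))
  msd <- mean_surface_displacement(fits, 25, force_fit = as_polyfit("R3"),
                                   region = "R3")
  grid <- seq(msd$x_min_mm, 45, by = 1)
  expect_lt(max(abs(poly_eval(msd$coefficients, grid) - poly_eval(cf, grid))), 0.3)
  # printed R3/25 row: x_max is the positive root of the stored cubic
  row <- as_mean_surface("R3", 25)
  root <- pick_plane_root(row$coefficients, row$x_min_mm, 110)
  expect_equal(root, 60.609, tolerance = 0.05)
  # f* at delta_I = 12.5 matches the mean force fit
  expect_equal(evaluate_fit(as_polyfit("R3"), 12.5), 2.92, tolerance = 5e-3)
  expect_equal(as_mean_surface("R3", 12.5)$f_star_n, 2.92)
})

test_that("stored reference rows are internally consistent", {
  tab <- reference_surface_profiles()
  resid <- vapply(seq_len(nrow(tab)), function(i) {
    poly_eval(c(tab$u1[i], tab$u2[i], tab$u3[i], tab$u4[i]), tab$x_max_mm[i])
  }, numeric(1))
  odd <- tab$region == "A1" & tab$delta_i_mm == 12
  # every row closes its reference-plane root except the one row whose
  # printed constant term is internally inconsistent
  expect_true(all(abs(resid[!odd]) < 0.05))
  expect_gt(abs(resid[odd]), 1)
  expect_true(all(tab$x_min_mm >= 6 & tab$x_min_mm <= 10))
})

test_that("composed profiles are continuous from tip apex to the far field", {
  msd <- as_mean_surface("R3", 25)
  f <- compose_full_profile(msd)
  expect_equal(f(0), -25)
  expect_equal(f(110), 0)
  x <- seq(0, 110, by = 0.1)
  v <- f(x)
  # continuity on a dense grid: adjacent differences bounded by slope * h
  expect_lt(max(abs(diff(v))), 0.35)
  # all rows compose without gaps
  tab <- reference_surface_profiles()
  for (i in seq_len(nrow(tab))) {
    fi <- compose_full_profile(as_mean_surface(tab[i, ]))
    vi <- fi(x)
    expect_equal(fi(0), -tab$delta_i_mm[i])
    expect_lt(max(abs(diff(vi))), 0.5)
  }
})

test_that("mirroring all inputs leaves the mean profile unchanged", {
  cf <- c(-5e-05, 4e-03, 2.4e-01, -16)
  xs <- seq(10, 45, by = 2.5)
  zs <- poly_eval(cf, xs)
  pts <- dplyr::bind_rows(
    tibble::tibble(side = "right", x_mm = xs, z_mm = zs + 0.2),
    tibble::tibble(side = "left", x_mm = -xs, z_mm = zs - 0.2))
  mirrored <- pts
  mirrored$side <- ifelse(pts$side == "left", "right", "left")
  mirrored$x_mm <- -pts$x_mm
  build <- function(p) {
    fits <- list(side_profile_fit(p, 25, "right"),
                 side_profile_fit(p, 25, "left"))
    mean_surface_displacement(fits, 25)
  }
  a <- build(pts)
  b <- build(mirrored)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-9)
  expect_equal(a$x_max_mm, b$x_max_mm, tolerance = 1e-9)
})

test_that("trim factor maps to the lateral evaluation bound", {
  msd <- as_mean_surface("R3", 25)
  xt <- x_trim_from_delta(msd, 0.5)
  # independent oracle: root bracketing on the printed cubic shifted by +0.5
  oracle <- uniroot(function(x) poly_eval(msd$coefficients, x) + 0.5,
                    c(msd$x_min_mm, msd$x_max_mm))$root
  expect_equal(xt, oracle, tolerance = 1e-6)
  expect_true(xt > msd$x_min_mm && xt < msd$x_max_mm)
})
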