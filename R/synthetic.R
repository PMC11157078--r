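# Synthetic experiments: ground-truth forward solutions wrapped in
# instrument noise, so every pipeline stage is testable without the human
# study.

# run code under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Instrument noise specification
#'
#' Noise envelope of the synthetic measurement chain: Gaussian force noise
#' on the load cell (the calibration-scale RMSE of about 0.4 N), additive
#' ToF distance noise with a target RMSE of about 0.8 mm clipped to the
#' absolute deviation bound of +-1.6 mm, and the resting sEMG baseline
#' amplitude. Generation is reproducible per seed.
#'
#' @param force_sd_n Load-cell noise SD, N.
#' @param tof_rmse_mm Target ToF distance noise RMSE, mm.
#' @param tof_bound_mm Clipping bound of the ToF noise, mm.
#' @param semg_baseline_uv Resting sEMG RMS amplitude, microvolts.
#' @param seed Integer seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(force_sd_n = 0.4, tof_rmse_mm = 0.805,
                       tof_bound_mm = 1.6, semg_baseline_uv = 6.8,
                       seed = 1L) {
  assert_that(force_sd_n >= 0 && tof_rmse_mm >= 0 && tof_bound_mm >= 0,
              "noise bounds must be nonnegative")
  structure(
    list(force_sd_n = force_sd_n, tof_rmse_mm = tof_rmse_mm,
         tof_bound_mm = tof_bound_mm, semg_baseline_uv = semg_baseline_uv,
         seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Generate a synthetic indenter force-displacement stream
#'
#' Emulates one indenter recording from a forward solution: the indenter
#' displacement ramps at the feed rate of 5 mm/s, the force samples the
#' solution's reaction curve (monotone interpolation) plus Gaussian load
#' cell noise, and a leading zero-force pre-contact prefix is included to
#' exercise record cleaning.
#'
#' @param solution An [solve_indentation()] result (ground truth).
#' @param noise A [noise_spec()].
#' @param seed Seed (defaults to the noise spec's).
#' @param feed_mm_s Feed rate.
#' @param rate_hz Sampling rate of the stream.
#' @param pre_contact_s Length of the pre-contact prefix.
#' @return A tibble `t_s`, `delta_mm`, `force_n`.
#' @export
generate_force_stream <- function(solution, noise = noise_spec(),
                                  seed = NULL, feed_mm_s = 5,
                                  rate_hz = 100, pre_contact_s = 0.5) {
  stopifnot(inherits(solution, "indentation_solution"))
  seed <- seed %||% noise$seed
  h <- solution$history
  ffun <- splinefun(h$delta_mm, h$reaction_n, method = "monoH.FC")
  d_max <- max(h$delta_mm)
  t_ramp <- d_max / feed_mm_s
  t <- seq(0, pre_contact_s + t_ramp, by = 1 / rate_hz)
  delta <- pmax(0, (t - pre_contact_s) * feed_mm_s)
  delta <- pmin(delta, d_max)
  force <- ffun(delta)
  force[t < pre_contact_s] <- 0
  if (noise$force_sd_n > 0) {
    eps <- with_seed(seed, rnorm(length(t), sd = noise$force_sd_n))
    force <- ifelse(t < pre_contact_s, force, force + eps)
  }
  tibble::tibble(t_s = t, delta_mm = delta, force_n = force)
}

#' Render synthetic ToF frames of an axisymmetric surface
#'
#' Ray-casts the 8x8 zone grid of each tilted sensor through its frustum
#' onto an axisymmetric surface function, returning the absolute distances
#' the sensors would measure, plus clipped additive noise, at 15 Hz
#' timestamps. Zones whose rays miss the surface are flagged invalid
#' (dropped).
#'
#' @param surface_fun Vectorized surface height `z(x)` (mm, negative below
#'   the reference plane) on radii `0..r_c_mm`; the reference plane
#'   continues beyond.
#' @param geometry A [tof_sensor_geometry()].
#' @param noise A [noise_spec()].
#' @param seed Seed (defaults to the noise spec's).
#' @param times_s Frame timestamps (default a single frame at t = 0; pass
#'   e.g. `seq(0, 2, by = 1/15)` for a stream).
#' @param r_c_mm Extent of the surface function.
#' @return A frame tibble `side`, `t_s`, `row`, `col`, `distance_mm`.
#' @export
render_tof_frames <- function(surface_fun, geometry = tof_sensor_geometry(),
                              noise = noise_spec(), seed = NULL,
                              times_s = 0, r_c_mm = 110) {
  seed <- seed %||% noise$seed
  zones <- tidyr::expand_grid(
    side = c("left", "right"),
    row = seq_len(geometry$n_zones),
    col = seq_len(geometry$n_zones))
  surf <- function(r) ifelse(r <= r_c_mm, surface_fun(r), 0)
  cast_one <- function(side, row, col) {
    ray <- tof_zone_ray(geometry, side, row, col)
    g <- function(s) {
      p <- ray$origin + s * ray$dir
      p[3] - surf(sqrt(p[1]^2 + p[2]^2))
    }
    lo <- 1e-3
    hi <- (geometry$standoff_mm + 80) / abs(ray$dir[3])
    if (g(lo) <= 0 || g(hi) >= 0) return(NA_real_)
    uniroot(g, c(lo, hi), tol = 1e-8)$root
  }
  zones$distance_mm <- purrr::pmap_dbl(zones, cast_one)
  zones <- zones[is.finite(zones$distance_mm), ]
  frames <- tidyr::expand_grid(t_s = times_s, zones)
  if (noise$tof_rmse_mm > 0) {
    eps <- with_seed(seed, rnorm(nrow(frames), sd = noise$tof_rmse_mm))
    eps <- pmin(pmax(eps, -noise$tof_bound_mm), noise$tof_bound_mm)
    frames$distance_mm <- frames$distance_mm + eps
  }
  frames[, c("side", "t_s", "row", "col", "distance_mm")]
}

#' Generate a synthetic sEMG trace
#'
#' Band-limited (45-500 Hz) Gaussian noise whose RMS amplitude is modulated
#' by a muscle-activity profile over a calibrated MVC amplitude, with a
#' 50 Hz mains component added to exercise the notch filter.
#'
#' @param activity_pct Activity profile in percent of MVC: a scalar or a
#'   vector resampled over the trace duration (0-150).
#' @param noise A [noise_spec()] (sets the resting baseline amplitude).
#' @param seed Seed (defaults to the noise spec's).
#' @param duration_s Trace length.
#' @param fs_hz Sampling rate.
#' @param mvc_uv RMS amplitude at 100% MVC.
#' @param mains_uv Amplitude of the 50 Hz mains contamination.
#' @return A tibble `t_s`, `uv`.
#' @export
generate_semg <- function(activity_pct, noise = noise_spec(), seed = NULL,
                          duration_s = 4, fs_hz = 1024, mvc_uv = 235.4,
                          mains_uv = 10) {
  assert_that(all(activity_pct >= 0 & activity_pct <= 150),
              "activity profile must lie in [0, 150] %")
  seed <- seed %||% noise$seed
  n <- round(duration_s * fs_hz)
  t <- seq_len(n) / fs_hz
  act <- if (length(activity_pct) == 1L) rep(activity_pct, n) else
    approx(seq(0, duration_s, length.out = length(activity_pct)),
           activity_pct, xout = t, rule = 2)$y
  amp <- noise$semg_baseline_uv +
    (mvc_uv - noise$semg_baseline_uv) * act / 100
  raw <- with_seed(seed, rnorm(n))
  nyq <- fs_hz / 2
  bp <- signal::butter(4, c(45, 500) / nyq, type = "pass")
  shaped <- signal::filtfilt(bp, raw)
  shaped <- shaped / sqrt(mean(shaped^2))
  uv <- shaped * amp + mains_uv * sin(2 * pi * 50 * t)
  tibble::tibble(t_s = t, uv = uv)
}

#' Build a suite of synthetic experiments
#'
#' Generates complete synthetic experiments (force stream, ToF frame
#' streams of both sensors, sEMG trace) for combinations of ground-truth
#' Ogden parameter sets and region configurations, writes them as CSV
#' fixtures under `dir` with a JSON manifest holding the ground truth, and
#' returns the collection invisibly. Re-running with the same seed yields
#' identical fixtures.
#'
#' @param param_sets List of [ogden_params()] ground truths.
#' @param delta_max_mm Maximum indentation depth per experiment (recycled).
#' @param noise A [noise_spec()].
#' @param dir Output directory (created).
#' @param N Mesh refinement used for the ground-truth forward solves.
#' @param n_steps Forward load steps.
#' @param activity_pct Muscle-activity level for the sEMG trace.
#' @return Invisibly, a list of experiments, each holding `params`,
#'   `solution`, `force_stream`, `frames`, `reference_frames`, `semg`.
#' @export
build_experiment_suite <- function(param_sets, delta_max_mm = 20,
                                   noise = noise_spec(), dir = NULL,
                                   N = 2L, n_steps = 8L, activity_pct = 5) {
  delta_max_mm <- rep_len(delta_max_mm, length(param_sets))
  geometry <- tof_sensor_geometry()
  mesh <- build_mesh(mesh_spec(N = N))
  experiments <- lapply(seq_along(param_sets), function(i) {
    p <- param_sets[[i]]
    seed_i <- noise$seed + i
    sol <- solve_indentation(mesh, p, delta_max_mm[i], n_steps = n_steps)
    d_max <- delta_max_mm[i]
    prof <- surface_profile(sol, d_max)
    u_fun <- splinefun(prof$r_mm, prof$u_mm, method = "monoH.FC")
    # deformed surface: indenter tip footprint, then the solved profile
    surface_fun <- function(x) {
      tip <- indenter_tip_profile(x, d_max)
      u <- u_fun(x)
      ifelse(!is.na(tip) & tip < u, tip, u)
    }
    list(
      params = p,
      delta_max_mm = d_max,
      seed = seed_i,
      solution = sol,
      force_stream = generate_force_stream(sol, noise, seed = seed_i),
      reference_frames = render_tof_frames(function(x) rep(0, length(x)),
                                           geometry, noise, seed = seed_i + 1000L),
      frames = render_tof_frames(surface_fun, geometry, noise,
                                 seed = seed_i + 2000L),
      semg = generate_semg(activity_pct, noise, seed = seed_i + 3000L)
    )
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- lapply(seq_along(experiments), function(i) {
      ex <- experiments[[i]]
      base <- file.path(dir, sprintf("exp%02d", i))
      utils::write.csv(ex$force_stream, paste0(base, "_force.csv"),
                       row.names = FALSE)
      utils::write.csv(ex$frames, paste0(base, "_tof.csv"), row.names = FALSE)
      utils::write.csv(ex$reference_frames, paste0(base, "_tof_ref.csv"),
                       row.names = FALSE)
      utils::write.csv(ex$semg, paste0(base, "_semg.csv"), row.names = FALSE)
      list(id = sprintf("exp%02d", i),
           c_kpa = ex$params$c_kpa, m = ex$params$m,
           kappa_kpa = ex$params$kappa_kpa,
           delta_max_mm = ex$delta_max_mm, seed = ex$seed)
    })
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(experiments)
}
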