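#' Time-of-flight sensor geometry
#'
#' Pose and per-zone ray model of the two 8x8 multi-zone ToF distance sensors
#' observing the skin beside the indenter tip. Each sensor sits
#' `standoff_mm` above the reference plane, tilted `tilt_deg` outward from
#' the vertical, with a square 8x8 zone grid spanning a `fov_diag_deg`
#' diagonal field of view. The sensors are mounted sagittal-symmetrically;
#' the lateral origin offset is chosen so the innermost zone ray of the
#' transverse measurement row meets the reference plane at the indenter tip
#' radius. Row 5 (the transverse row used for profile reconstruction) lies
#' exactly in the measurement plane; the remaining rows fan out of plane in
#' zone-pitch steps. The synthetic frame renderer and the inverse
#' transformation share this one geometry definition.
#'
#' @param tilt_deg Sensor tilt from vertical, degrees.
#' @param standoff_mm Sensor height above the reference plane, mm.
#' @param fov_diag_deg Diagonal field of view, degrees.
#' @param n_zones Zones per side of the square grid.
#' @param r_t_mm Indenter tip radius, mm.
#' @return An object of class `tof_geometry`.
#' @export
tof_sensor_geometry <- function(tilt_deg = 12, standoff_mm = 35.1,
                                fov_diag_deg = 63, n_zones = 8L,
                                r_t_mm = 10) {
  fov_axis <- fov_diag_deg / sqrt(2)
  pitch <- fov_axis / n_zones
  # column angles from vertical, increasing outward; zone centers
  col_angle <- tilt_deg + (seq_len(n_zones) - (n_zones + 1) / 2) * pitch
  # row 5 exactly in the transverse plane
  row_angle <- (seq_len(n_zones) - 5) * pitch
  # innermost column ray lands on the reference plane at x = r_t
  x_s <- r_t_mm - standoff_mm * tanpi(min(col_angle) / 180)
  structure(
    list(
      tilt_deg = tilt_deg, standoff_mm = standoff_mm,
      fov_diag_deg = fov_diag_deg, n_zones = n_zones, r_t_mm = r_t_mm,
      pitch_deg = pitch, col_angle_deg = col_angle,
      row_angle_deg = row_angle, x_origin_mm = x_s
    ),
    class = "tof_geometry"
  )
}

# Ray origin (3-vector) and unit direction for zone (row, col) of one side.
tof_zone_ray <- function(geometry, side, row, col) {
  sgn <- if (side == "left") -1 else 1
  th <- geometry$col_angle_deg[col] * pi / 180
  be <- geometry$row_angle_deg[row] * pi / 180
  d <- c(sgn * tan(th), tan(be), -1)
  d <- d / sqrt(sum(d^2))
  list(origin = c(sgn * geometry$x_origin_mm, 0, geometry$standoff_mm),
       dir = d)
}

#' Smooth and resample raw ToF frames
#'
#' Replaces each zone distance by the mean over a length-5 sliding window
#' across the neighboring zones of its row, then resamples every zone's time
#' series to a uniform 0.1 s grid by linear interpolation.
#'
#' @param frames Tidy frame stream: tibble with columns `side`, `t_s`,
#'   `row`, `col`, `distance_mm`.
#' @param window Spatial smoothing window (zones).
#' @param dt_s Resampling interval, seconds.
#' @param max_gap_s Largest tolerated gap between frames.
#' @return A tibble with the same columns on the uniform time grid.
#' @export
preprocess_frames <- function(frames, window = 5L, dt_s = 0.1,
                              max_gap_s = 1.0) {
  needed <- c("side", "t_s", "row", "col", "distance_mm")
  assert_that(all(needed %in% names(frames)), "malformed frame stream")
  half <- (window - 1L) %/% 2L
  smoothed <- frames |>
    dplyr::group_by(.data$side, .data$t_s, .data$row) |>
    dplyr::arrange(.data$col, .by_group = TRUE) |>
    dplyr::mutate(distance_mm = vapply(seq_along(.data$col), function(i) {
      w <- max(1L, i - half):min(dplyr::n(), i + half)
      mean(.data$distance_mm[w])
    }, numeric(1))) |>
    dplyr::ungroup()
  # uniform time grid per sensor
  out <- smoothed |>
    dplyr::group_by(.data$side) |>
    dplyr::group_modify(function(d, key) {
      ts <- sort(unique(d$t_s))
      if (length(ts) > 1L) {
        assert_that(max(diff(ts)) <= max_gap_s, "gap longer than 1 s in frame stream")
      }
      grid <- seq(ts[1], ts[length(ts)], by = dt_s)
      d |>
        dplyr::group_by(.data$row, .data$col) |>
        dplyr::group_modify(function(g, key) {
          tibble::tibble(
            t_s = grid,
            distance_mm = if (nrow(g) == 1L) rep(g$distance_mm, length(grid)) else
              approx(g$t_s, g$distance_mm, xout = grid, rule = 2)$y)
        }) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(needed))
  out
}

#' Convert ToF frames to transverse surface points
#'
#' Converts the row-5 zone distances of both sensors into lateral/vertical
#' coordinates `(x, z)` in the transverse plane via the shared sensor ray
#' model: each distance places a point along its zone ray; the vertical
#' displacement `z` is taken relative to the same zone's reference-frame
#' (zero-position) point, so a frame identical to the reference maps to
#' `z = 0` everywhere. Left-side points carry negative `x`.
#'
#' @param frames Preprocessed frame tibble (one timestamp per side, or pass
#'   a `t_s` filtered stream).
#' @param geometry A [tof_sensor_geometry()].
#' @param reference_frames Frame tibble captured at the indenter zero
#'   position.
#' @param row Transverse measurement row.
#' @return Tibble `side`, `x_mm`, `z_mm` (and `t_s` when several timestamps
#'   are present), `x` strictly ordered per side.
#' @export
to_transverse_points <- function(frames, geometry, reference_frames,
                                 row = 5L) {
  assert_that(!is.null(reference_frames) && nrow(reference_frames) > 0,
              "missing reference (zero-position) frames")
  cast <- function(d) {
    d <- d[d$row == row, ]
    pts <- purrr::pmap(
      list(d$side, d$col, d$distance_mm),
      function(side, col, dist) {
        ray <- tof_zone_ray(geometry, side, row, col)
        p <- ray$origin + dist * ray$dir
        c(x = sqrt(p[1]^2 + p[2]^2) * (if (side == "left") -1 else 1), z = p[3])
      }
    )
    d$x_mm <- vapply(pts, `[[`, numeric(1), "x")
    d$z_mm <- vapply(pts, `[[`, numeric(1), "z")
    d
  }
  def <- cast(frames)
  ref <- cast(reference_frames) |>
    dplyr::group_by(.data$side, .data$col) |>
    dplyr::summarise(z_ref = mean(.data$z_mm), .groups = "drop")
  out <- def |>
    dplyr::left_join(ref, by = c("side", "col")) |>
    dplyr::mutate(z_mm = .data$z_mm - .data$z_ref)
  keep <- c(if (length(unique(out$t_s)) > 1L) "t_s", "side", "x_mm", "z_mm")
  out <- out[order(out$side, out$x_mm), keep, drop = FALSE]
  tibble::as_tibble(out)
}

#' Indenter tip surface profile
#'
#' Vertical profile of the rigid indenter tip at depth `delta_mm`: a
#' hemisphere of radius `r_t_mm` whose apex sits `delta_mm` below the
#' reference plane, continued by the vertical wall of a 20 mm cylinder
#' section at `x = r_t`.
#'
#' @param x_mm Radial distance(s) from the indenter axis.
#' @param delta_mm Indentation depth.
#' @param r_t_mm Tip radius.
#' @return `z(x)` in mm (negative below the reference plane); `NA` outside
#'   the tip footprint.
#' @export
indenter_tip_profile <- function(x_mm, delta_mm, r_t_mm = 10) {
  z <- rep(NA_real_, length(x_mm))
  inside <- abs(x_mm) <= r_t_mm
  z[inside] <- -delta_mm + (r_t_mm - sqrt(r_t_mm^2 - x_mm[inside]^2))
  z
}

# Pick the root of a (shifted) cubic on the reference plane:
# real roots in (lower, upper]; among them the smallest with positive slope,
# else the largest.
pick_plane_root <- function(coefficients, lower, upper) {
  r <- poly_real_roots(coefficients)
  r <- r[r > lower + 1e-9 & r <= upper + 1e-9]
  if (length(r) == 0L) return(NA_real_)
  dcf <- poly_deriv(coefficients)
  up <- r[poly_eval(dcf, r) > 0]
  if (length(up) > 0) min(up) else max(r)
}

# Intersection of a side profile curve (function of |x|) with the tip
# profile at depth delta: root on (0, r_t], else the wall at x = r_t when
# the curve value there lies on the wall segment.
tip_intersection <- function(fun, delta_mm, r_t_mm = 10) {
  g <- function(x) fun(x) - indenter_tip_profile(x, delta_mm, r_t_mm)
  xs <- seq(1e-6, r_t_mm - 1e-9, length.out = 200)
  gv <- g(xs)
  sc <- which(diff(sign(gv)) != 0)
  if (length(sc) > 0) {
    i <- sc[length(sc)]  # outermost crossing = separation point
    x0 <- uniroot(g, c(xs[i], xs[i + 1]))$root
    return(list(x = x0, z = fun(x0)))
  }
  zw <- fun(r_t_mm)
  if (zw >= -delta_mm + r_t_mm - 1e-9 && zw <= 1e-9) {
    return(list(x = r_t_mm, z = zw))
  }
  NULL
}

#' Fit a one-sided cubic surface-displacement profile
#'
#' Fits the third-degree polynomial `v(x)` describing one side's transverse
#' surface displacement at indentation depth `delta_i_mm` by the base-point
#' sweep: (1) ToF points with `|x| <= 0.9 r_t` are discarded as distorted;
#' (2) the straight line joining the innermost remaining left and right
#' points is intersected with the indenter tip profile, giving an anchor
#' point per side; (3) a cubic is fitted per candidate to the side's ToF
#' points, its anchor, and three base points at `z = 0` equally spaced over
#' an 8 mm interval ending at the candidate position `x_B`; (4) `x_B` is
#' swept in 5 mm steps from the outermost ToF point (inclusive) up to
#' `r_C`; (5) the candidate minimizing the cost `Theta(x_B) = RMSE + Q` is
#' returned, where the RMSE is computed over the ToF measuring points only
#' and `Q = 0.75 x_xmax / r_C` if the cubic meets the reference plane within
#' `r_C`, else `Q = 10`. Ties go to the smallest `x_B`.
#'
#' @param points Transverse points of *both* sides (tibble `side`, `x_mm`,
#'   `z_mm`); the anchor construction needs both, the cubic is fitted for
#'   `side`.
#' @param delta_i_mm Indentation depth.
#' @param side Which side to fit.
#' @param r_t_mm,r_c_mm Tip radius and model/ROI radius.
#' @param discard_fraction Inner discard bound as a fraction of `r_t`.
#' @param base_interval_mm Width of the base-point interval.
#' @param step_mm Sweep step of `x_B`.
#' @return An object of class `side_profile`: `side`, `delta_i_mm`,
#'   `coefficients` (descending cubic in `|x|`), `x_b_mm`, `theta`, `rmse`,
#'   `q`, `x_xmax_mm` (`NA` when no intersection exists; `penalized` flag
#'   set), `anchor`, and the fitted points.
#' @export
side_profile_fit <- function(points, delta_i_mm, side = c("right", "left"),
                             r_t_mm = 10, r_c_mm = 110,
                             discard_fraction = 0.9, base_interval_mm = 8,
                             step_mm = 5) {
  side <- match.arg(side)
  pts <- points[abs(points$x_mm) > discard_fraction * r_t_mm, , drop = FALSE]
  sp <- pts[pts$side == side, , drop = FALSE]
  assert_that(nrow(sp) >= 3, "need at least 3 points per side after discarding")
  # anchor: line through the innermost left and right points, cut with the tip
  il <- pts[pts$side == "left", , drop = FALSE]
  ir <- pts[pts$side == "right", , drop = FALSE]
  anchor <- NULL
  if (nrow(il) > 0 && nrow(ir) > 0) {
    pl <- il[which.max(il$x_mm), ]
    pr <- ir[which.min(ir$x_mm), ]
    slope <- (pr$z_mm - pl$z_mm) / (pr$x_mm - pl$x_mm)
    line_abs <- function(s) {
      x <- if (side == "left") -s else s
      pl$z_mm + slope * (x - pl$x_mm)
    }
    anchor <- tip_intersection(line_abs, delta_i_mm, r_t_mm)
  }
  s_obs <- abs(sp$x_mm)
  z_obs <- sp$z_mm
  ord <- order(s_obs)
  s_obs <- s_obs[ord]; z_obs <- z_obs[ord]
  s_fit <- c(if (!is.null(anchor)) anchor$x, s_obs)
  z_fit <- c(if (!is.null(anchor)) anchor$z, z_obs)

  xb_candidates <- seq(max(s_obs), r_c_mm, by = step_mm)
  best <- NULL
  nb <- 3L
  base_off <- seq(-base_interval_mm, 0, length.out = nb)
  for (xb in xb_candidates) {
    sx <- c(s_fit, xb + base_off)
    sz <- c(z_fit, rep(0, nb))
    X <- cbind(sx^3, sx^2, sx, 1)
    cf <- tryCatch(qr.solve(X, sz), error = function(e) NULL)
    if (is.null(cf)) next
    cf <- as.numeric(cf)
    rmse <- sqrt(mean((poly_eval(cf, s_obs) - z_obs)^2))
    xxmax <- pick_plane_root(cf, if (!is.null(anchor)) anchor$x else 0, r_c_mm)
    q <- if (is.na(xxmax)) 10 else 0.75 * xxmax / r_c_mm
    theta <- rmse + q
    if (is.null(best) || theta < best$theta - 1e-12) {
      best <- list(coefficients = cf, x_b_mm = xb, theta = theta,
                   rmse = rmse, q = q, x_xmax_mm = xxmax)
    }
  }
  assert_that(!is.null(best), "no base-point candidate admits a cubic fit")
  structure(
    c(best, list(
      side = side, delta_i_mm = delta_i_mm,
      penalized = is.na(best$x_xmax_mm),
      anchor = anchor,
      points = tibble::tibble(x_mm = s_obs, z_mm = z_obs)
    )),
    class = "side_profile"
  )
}

#' @export
print.side_profile <- function(x, ...) {
  cat(sprintf(
    "<side_profile> %s side, delta_I = %.4g mm, x_B = %.4g mm, Theta = %.4g%s\n",
    x$side, x$delta_i_mm, x$x_b_mm, x$theta,
    if (x$penalized) " (no plane intersection: penalized)" else ""
  ))
  invisible(x)
}

#' Construct a mean-surface object
#'
#' Builds a `mean_surface` (region-mean cubic surface-displacement profile)
#' either from its fields or from a bundled reference row.
#'
#' @param x Either a one-row tibble as returned by
#'   [reference_surface_profiles()], or a region label (then `delta_i_mm`
#'   selects the row).
#' @param delta_i_mm Indentation depth used for the lookup form.
#' @return An object of class `mean_surface` with fields `region`,
#'   `delta_i_mm`, `coefficients`, `x_min_mm`, `x_max_mm`, `f_star_n`.
#' @export
as_mean_surface <- function(x, delta_i_mm = NULL) {
  if (is.character(x) && length(x) == 1L) {
    tab <- reference_surface_profiles()
    sel <- tab$region == x
    if (!is.null(delta_i_mm)) sel <- sel & abs(tab$delta_i_mm - delta_i_mm) < 1e-9
    x <- tab[sel, ]
    assert_that(nrow(x) == 1L, "no unique reference surface row for that lookup")
  }
  structure(
    list(
      region = x$region, delta_i_mm = x$delta_i_mm,
      coefficients = c(x$u1, x$u2, x$u3, x$u4),
      x_min_mm = x$x_min_mm, x_max_mm = x$x_max_mm, f_star_n = x$f_star_n
    ),
    class = "mean_surface"
  )
}

#' Region-mean surface displacement from side profile fits
#'
#' Combines the per-participant, per-side cubic fits of one region at one
#' indentation depth into the region-mean profile: left-side fits are
#' mirrored to positive `x`, every fit is sampled densely over its valid
#' range, and a single cubic is fitted over all samples. `x_min` is set as
#' the intersection of the mean cubic with the indenter tip profile
#' (hemisphere, or the cylinder wall at `r_t` when the cubic passes above
#' the equator) and `x_max` as its root on the reference plane. The
#' reference force `f*` is attached from the region's mean force fit.
#'
#' @param fits List of [side_profile_fit()] results (both sides, all
#'   participants).
#' @param delta_i_mm Indentation depth.
#' @param force_fit Optional `polyfit` used to attach `f* = f(delta_I)`.
#' @param region Region label.
#' @param r_t_mm,r_c_mm Tip radius and model radius.
#' @param sample_mm Sampling step along each side curve.
#' @return A `mean_surface` object (see [as_mean_surface()]).
#' @export
mean_surface_displacement <- function(fits, delta_i_mm, force_fit = NULL,
                                      region = NA_character_, r_t_mm = 10,
                                      r_c_mm = 110, sample_mm = 1) {
  assert_that(length(fits) >= 1, "need at least one side profile fit")
  sides <- vapply(fits, `[[`, character(1), "side")
  assert_that(all(c("left", "right") %in% sides) || length(unique(sides)) == 1L,
              "expected fits from both sides")
  samples <- purrr::map_dfr(fits, function(f) {
    lo <- if (!is.null(f$anchor)) f$anchor$x else 0.9 * r_t_mm
    hi <- if (!is.na(f$x_xmax_mm)) f$x_xmax_mm else f$x_b_mm
    s <- seq(lo, hi, by = sample_mm)
    tibble::tibble(x = s, z = poly_eval(f$coefficients, s))
  })
  X <- cbind(samples$x^3, samples$x^2, samples$x, 1)
  cf <- as.numeric(qr.solve(X, samples$z))
  ufun <- function(x) poly_eval(cf, x)
  ti <- tip_intersection(ufun, delta_i_mm, r_t_mm)
  assert_that(!is.null(ti), "mean cubic does not intersect the indenter tip profile")
  x_min <- ti$x
  x_max <- pick_plane_root(cf, x_min, r_c_mm)
  assert_that(is.finite(x_max), "mean cubic does not return to the reference plane")
  f_star <- if (!is.null(force_fit)) evaluate_fit(force_fit, delta_i_mm) else NA_real_
  structure(
    list(region = region, delta_i_mm = delta_i_mm, coefficients = cf,
         x_min_mm = x_min, x_max_mm = x_max, f_star_n = f_star),
    class = "mean_surface"
  )
}

#' @export
print.mean_surface <- function(x, ...) {
  cat(sprintf(
    "<mean_surface>%s delta_I = %.4g mm, x in [%.3f, %.3f] mm, f* = %.3g N\n",
    if (!is.na(x$region)) paste0(" [", x$region, "]") else "",
    x$delta_i_mm, x$x_min_mm, x$x_max_mm, x$f_star_n
  ))
  invisible(x)
}

# C1 cubic Hermite on [x0, x1] matching (y0, s0) and (y1, s1).
hermite_blend <- function(x, x0, x1, y0, y1, s0, s1) {
  h <- x1 - x0
  t <- (x - x0) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y0 + h10 * h * s0 + h01 * y1 + h11 * h * s1
}

#' Compose the full piecewise surface-displacement profile
#'
#' Extends a region-mean cubic to the complete displacement function on
#' `[0, r_C]`: the indenter tip profile for `x < x_min`, the cubic on
#' `[x_min, x_max]`, and the undeformed reference plane beyond `x_max`. The
#' transitions at `x_min` and `x_max` are smoothed with cubic Hermite blends
#' over sections of up to `blend_mm`, matching value and slope at both blend
#' ends so the composed curve is C1-continuous.
#'
#' @param msd A `mean_surface`.
#' @param blend_mm Maximum width of each smoothing section.
#' @param r_t_mm,r_c_mm Tip radius and model radius.
#' @return A vectorized function `u(x)` (mm, negative below the plane) with
#'   `u(0) = -delta_I` and `u(r_C) = 0`.
#' @export
compose_full_profile <- function(msd, blend_mm = 10, r_t_mm = 10,
                                 r_c_mm = 110) {
  stopifnot(inherits(msd, "mean_surface"))
  cf <- msd$coefficients
  dcf <- poly_deriv(cf)
  delta <- msd$delta_i_mm
  x_min <- msd$x_min_mm
  x_max <- msd$x_max_mm
  tipf <- function(x) indenter_tip_profile(x, delta, r_t_mm)
  tipd <- function(x) x / sqrt(pmax(r_t_mm^2 - x^2, 1e-9))
  # blend across the tip transition
  hA <- min(blend_mm, x_min, (x_max - x_min) / 2)
  xa0 <- min(x_min - hA / 2, r_t_mm - 0.5)
  xa1 <- x_min + hA / 2
  # blend across the reference-plane transition
  hB <- min(blend_mm, (x_max - xa1) / 2, 2 * (r_c_mm - x_max))
  xb0 <- x_max - hB / 2
  xb1 <- x_max + hB / 2
  function(x) {
    out <- numeric(length(x))
    seg_tip <- x < xa0
    seg_ba <- x >= xa0 & x < xa1
    seg_cub <- x >= xa1 & x < xb0
    seg_bb <- x >= xb0 & x < xb1
    out[seg_tip] <- tipf(x[seg_tip])
    out[seg_ba] <- hermite_blend(x[seg_ba], xa0, xa1,
                                 tipf(xa0), poly_eval(cf, xa1),
                                 tipd(xa0), poly_eval(dcf, xa1))
    out[seg_cub] <- poly_eval(cf, x[seg_cub])
    out[seg_bb] <- hermite_blend(x[seg_bb], xb0, xb1,
                                 poly_eval(cf, xb0), 0,
                                 poly_eval(dcf, xb0), 0)
    out[x >= xb1] <- 0
    out
  }
}

#' Lateral evaluation bound from the trim factor
#'
#' Solves `|u(x)| = delta_trim` on a region-mean cubic: the trim factor is
#' the smallest reference displacement still considered reliable, and
#' `x_trim` is the lateral position where the reference profile decays to
#' it, bounding the surface-objective window `x_min <= x <= x_trim`.
#'
#' @param msd A `mean_surface`.
#' @param delta_trim_mm Trim factor in mm.
#' @return `x_trim` in mm.
#' @export
x_trim_from_delta <- function(msd, delta_trim_mm) {
  stopifnot(inherits(msd, "mean_surface"))
  cf <- msd$coefficients
  cf[length(cf)] <- cf[length(cf)] + delta_trim_mm
  r <- pick_plane_root(cf, msd$x_min_mm, msd$x_max_mm)
  assert_that(is.finite(r), "no x_trim root inside (x_min, x_max)")
  r
}

#' Plot a mean surface-displacement profile
#'
#' @param object A `mean_surface`.
#' @param n Number of samples.
#' @param ... Unused.
#' @return A ggplot of the composed profile with the valid cubic range
#'   marked.
#' @export
autoplot.mean_surface <- function(object, n = 400L, ...) {
  f <- compose_full_profile(object)
  d <- tibble::tibble(x_mm = seq(0, 110, length.out = n))
  d$z_mm <- f(d$x_mm)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_mm, y = .data$z_mm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(object$x_min_mm, object$x_max_mm),
                        linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = "x (mm)", y = "u (mm)",
      title = sprintf("Mean surface displacement%s, delta_I = %g mm",
                      if (!is.na(object$region)) paste0(" ", object$region) else "",
                      object$delta_i_mm)
    ) +
    ggplot2::theme_minimal()
}
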