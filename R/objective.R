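#' Normalized force residual
#'
#' Squared relative error between a simulated and a reference indentation
#' force at one depth: `F_f = (f_sim - f_ref)^2 / f_ref^2`.
#'
#' @param f_sim_n,f_ref_n Simulated and reference force, N.
#' @return Dimensionless residual.
#' @export
force_residual <- function(f_sim_n, f_ref_n) {
  assert_that(all(f_ref_n != 0), "reference force must be nonzero (stay above the toe region)")
  (f_sim_n - f_ref_n)^2 / f_ref_n^2
}

#' Inverse-radius node weights
#'
#' Weights the surface-objective nodes inversely proportional to their
#' initial radial coordinates. With `normalization = "sum"` (default) the
#' weights form a convex combination, `w_i = (1/r_i) / sum_j (1/r_j)`;
#' with `"norm"` the inverse-radius vector is scaled by its Euclidean
#' norm, `w_i = (1/r_i) / ||1/r||`, the scaling under which the combined
#' objective reproduces the reference identification landscape (see the
#' methods vignette).
#'
#' @param r_mm Initial node radii (> 0).
#' @param normalization `"sum"` or `"norm"`.
#' @return Weights (summing to 1 for `"sum"`).
#' @export
node_weights <- function(r_mm, normalization = c("sum", "norm")) {
  normalization <- match.arg(normalization)
  assert_that(length(r_mm) > 0, "empty node set")
  assert_that(all(r_mm > 0), "node radii must be positive")
  w <- 1 / r_mm
  if (normalization == "sum") w / sum(w) else w / sqrt(sum(w^2))
}

#' Normalized surface-displacement residual
#'
#' Weighted squared relative error between simulated and reference vertical
#' surface displacements at one depth:
#' `F_u = sum_i w_i (u_i_sim - u_i_ref)^2 / u_i_ref^2`, restricted to the
#' nodes inside the evaluation window `x_min <= x <= x_trim`. The window's
#' outer bound comes from the trim factor (the smallest reference
#' displacement still evaluated), which prevents the relative error from
#' blowing up where the reference displacement decays to zero.
#'
#' @param sim_profile Tibble `r_mm`, `u_mm` from [surface_profile()].
#' @param reference A `mean_surface` (reference cubic; the smoothed
#'   composed profile is evaluated at the node radii) or a list
#'   `list(u_fun, x_min_mm, x_trim_mm)`.
#' @param delta_trim_mm Trim factor, mm (ignored when `reference` carries
#'   an explicit window).
#' @param normalization Weight normalization passed to [node_weights()];
#'   the `"norm"` default is the reading under which the identification
#'   reproduces the reference optima and objective magnitudes.
#' @return Dimensionless residual.
#' @export
surface_residual <- function(sim_profile, reference, delta_trim_mm = 0.5,
                             normalization = "norm") {
  if (inherits(reference, "mean_surface")) {
    window <- list(
      u_fun = compose_full_profile(reference),
      x_min_mm = reference$x_min_mm,
      x_trim_mm = x_trim_from_delta(reference, delta_trim_mm)
    )
  } else {
    window <- reference
  }
  keep <- sim_profile$r_mm >= window$x_min_mm - 1e-9 &
    sim_profile$r_mm <= window$x_trim_mm + 1e-9
  assert_that(any(keep), "no surface node inside the evaluation window")
  r <- sim_profile$r_mm[keep]
  u_sim <- sim_profile$u_mm[keep]
  u_ref <- window$u_fun(r)
  w <- node_weights(r, normalization)
  sum(w * (u_sim - u_ref)^2 / u_ref^2)
}

#' Modulated combined objective
#'
#' Convex combination of the force and surface residuals at one depth:
#' `F_fu = eta * F_f + (1 - eta) * F_u`. `eta = 1` evaluates indentation
#' forces only, `eta = 0` surface displacements only.
#'
#' @param f_f,f_u Force and surface residuals.
#' @param eta Modulation factor in `[0, 1]`.
#' @return Combined residual.
#' @export
combined_objective <- function(f_f, f_u, eta = 0.5) {
  assert_that(all(eta >= 0 & eta <= 1), "eta must lie in [0, 1]")
  eta * f_f + (1 - eta) * f_u
}

#' Depth-averaged total objective
#'
#' Arithmetic mean of the combined objective over the four indentation
#' depth stations.
#'
#' @param f_fu Numeric vector of per-depth combined objectives (length 4).
#' @return Total objective.
#' @export
total_objective <- function(f_fu) {
  assert_that(length(f_fu) == 4L && all(is.finite(f_fu)),
              "need finite combined objectives at all four depths")
  mean(f_fu)
}

#' Reference set for the inverse identification of one region
#'
#' Bundles everything the objective needs for a region: the mean
#' force-displacement fit, the four mean surface-displacement profiles at
#' the depth stations `delta_I`, the region's `delta_max*`, trim factor and
#' default modulation factor.
#'
#' @param region Region label (`R1`-`R6`, `A1`-`A6`).
#' @param delta_trim_mm Trim factor; defaults to the region's identified
#'   value.
#' @param eta Default modulation factor.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(region, delta_trim_mm = NULL, eta = 0.5) {
  force_fit <- as_polyfit(region)
  surf <- reference_surface_profiles()
  surf <- surf[surf$region == region, ]
  assert_that(nrow(surf) == 4L, "expected four depth stations for the region")
  surf <- surf[order(surf$delta_i_mm), ]
  surfaces <- lapply(seq_len(4L), function(i) as_mean_surface(surf[i, ]))
  idp <- identified_parameters()
  idp <- idp[idp$region == region, ]
  if (is.null(delta_trim_mm)) delta_trim_mm <- idp$delta_trim_mm
  structure(
    list(region = region, force_fit = force_fit, surfaces = surfaces,
         delta_i_mm = surf$delta_i_mm,
         delta_max_star_mm = max(surf$delta_i_mm),
         f_star_n = surf$f_star_n,
         delta_trim_mm = delta_trim_mm, eta = eta),
    class = "reference_set"
  )
}

# Normalize a reference set (region tables or synthetic) to per-depth data:
# delta, f_ref, u_fun, x_min; x_trim resolved for a given trim factor.
ref_depth_data <- function(reference, delta_trim_mm) {
  lapply(seq_along(reference$delta_i_mm), function(i) {
    if (!is.null(reference$surfaces)) {
      ms <- reference$surfaces[[i]]
      list(delta = reference$delta_i_mm[i],
           f_ref = reference$f_star_n[i],
           window = list(
             u_fun = compose_full_profile(ms),
             x_min_mm = ms$x_min_mm,
             x_trim_mm = x_trim_from_delta(ms, delta_trim_mm)))
    } else {
      w <- reference$windows[[i]]
      list(delta = reference$delta_i_mm[i],
           f_ref = reference$f_star_n[i],
           window = list(
             u_fun = w$u_fun, x_min_mm = w$x_min_mm,
             x_trim_mm = w$x_trim_fun(delta_trim_mm)))
    }
  })
}

#' Synthetic reference set from a forward solution
#'
#' Wraps a forward-model solution as an inverse-identification reference:
#' reference forces are the simulated reactions at the four depth stations
#' and reference surface displacements interpolate the simulated top-edge
#' profiles. With the same forward model in the loop, the generating
#' parameter set attains an exactly zero objective, which is what makes
#' noiseless parameter-recovery tests sharp.
#'
#' @param solution An [solve_indentation()] result (solved to the desired
#'   `delta_max*` with recording steps hitting the four stations).
#' @param region Label carried through.
#' @param delta_trim_mm Trim factor stored on the set.
#' @param eta Default modulation factor.
#' @return A `reference_set`.
#' @export
synthetic_reference <- function(solution, region = "SYN",
                                delta_trim_mm = 0.5, eta = 0.5) {
  d4 <- solution$delta_i_mm
  windows <- lapply(d4, function(d) {
    p <- surface_profile(solution, d)
    fun <- splinefun(p$r_mm, p$u_mm, method = "monoH.FC")
    x_trim_fun <- function(dtrim) {
      # outermost radius where the reference displacement still reaches
      # the trim magnitude; collapses to the window start when the whole
      # profile is shallower than the candidate
      upper <- max(p$r_mm)
      xs <- seq(10, upper, by = 0.25)
      deep <- which(fun(xs) <= -dtrim)
      if (length(deep) == 0L) return(10)
      x0 <- xs[max(deep)]
      if (x0 >= upper) return(upper)
      uniroot(function(x) fun(x) + dtrim, c(x0, x0 + 0.25))$root
    }
    list(u_fun = fun, x_min_mm = 10, x_trim_fun = x_trim_fun)
  })
  structure(
    list(region = region, force_fit = NULL, surfaces = NULL,
         windows = windows, delta_i_mm = d4,
         delta_max_star_mm = max(d4),
         f_star_n = vapply(d4, function(d) reaction_at(solution, d), numeric(1)),
         delta_trim_mm = delta_trim_mm, eta = eta),
    class = "reference_set"
  )
}

#' Forward-solve a parameter grid
#'
#' Runs the forward indentation model for every parameter set of the grid
#' `P = C x M` and extracts what the objective needs: the reaction forces
#' and top-edge surface profiles at the four depth stations. Nonconverged
#' cells are recorded as failures; if more than `max_fail_frac` of the grid
#' fails the run aborts with a diagnostic.
#'
#' @param reference A [reference_set()].
#' @param c_kpa,m Grid axes (evenly spaced vectors).
#' @param N Mesh refinement factor.
#' @param n_steps Load steps to `delta_max*` (multiple of 4 so the steps
#'   hit the stations).
#' @param max_fail_frac Abort threshold on the nonconvergence fraction.
#' @param verbose Print progress.
#' @return An object of class `forward_grid`: tibble `cells` with columns
#'   `c_kpa`, `m`, `converged`, `f_sim` (list of 4 forces), `profiles`
#'   (list of 4 profile tibbles).
#' @export
forward_grid <- function(reference, c_kpa, m, N = 3L, n_steps = 8L,
                         max_fail_frac = 0.2, verbose = FALSE) {
  assert_that(n_steps %% 4L == 0L, "n_steps must be a multiple of 4")
  assert_that(length(c_kpa) > 0 && length(m) > 0, "empty grid")
  mesh <- build_mesh(mesh_spec(N = N))
  d4 <- reference$delta_max_star_mm * (1:4) / 4
  grid <- tidyr::expand_grid(c_kpa = sort(c_kpa), m = sort(m))
  res <- purrr::pmap(grid, function(c_kpa, m) {
    sol <- tryCatch(
      solve_indentation(mesh, ogden_params(c_kpa, m),
                        reference$delta_max_star_mm, n_steps = n_steps),
      error = function(e) NULL)
    if (is.null(sol)) {
      if (verbose) message(sprintf("  (%g kPa, %g): failed", c_kpa, m))
      return(list(converged = FALSE, f_sim = NULL, profiles = NULL))
    }
    if (verbose) {
      message(sprintf("  (%g kPa, %g): f(delta_max) = %.3f N", c_kpa, m,
                      reaction_at(sol, d4[4])))
    }
    list(converged = TRUE,
         f_sim = vapply(d4, function(d) reaction_at(sol, d), numeric(1)),
         profiles = lapply(d4, function(d) surface_profile(sol, d)))
  })
  grid$converged <- vapply(res, `[[`, logical(1), "converged")
  grid$f_sim <- lapply(res, `[[`, "f_sim")
  grid$profiles <- lapply(res, `[[`, "profiles")
  fail <- mean(!grid$converged)
  if (fail > max_fail_frac) {
    rlang::abort(sprintf(
      "%.0f%% of the parameter grid failed to converge", 100 * fail))
  }
  structure(list(cells = grid, delta_i_mm = d4, N = N, n_steps = n_steps),
            class = "forward_grid")
}

# residual evaluation of a forward grid against a reference
evaluate_objective <- function(forward, reference, eta, delta_trim_mm) {
  refs <- ref_depth_data(reference, delta_trim_mm)
  cells <- forward$cells
  nf <- nrow(cells)
  ff <- fu <- matrix(NA_real_, nf, 4)
  for (i in seq_len(nf)) {
    if (!cells$converged[i]) next
    for (k in 1:4) {
      ff[i, k] <- force_residual(cells$f_sim[[i]][k], refs[[k]]$f_ref)
      fu[i, k] <- surface_residual(cells$profiles[[i]][[k]], refs[[k]]$window)
    }
  }
  ffu <- combined_objective(ff, fu, eta)
  out <- tibble::tibble(
    c_kpa = cells$c_kpa, m = cells$m, converged = cells$converged)
  for (k in 1:4) {
    out[[paste0("f_f_", k)]] <- ff[, k]
    out[[paste0("f_u_", k)]] <- fu[, k]
    out[[paste0("f_fu_", k)]] <- ffu[, k]
  }
  out$f_fu_tot <- rowMeans(ffu)
  out
}

# lexicographic argmin (smallest value; ties to smaller c then smaller m)
argmin_cell <- function(tab, col) {
  ok <- which(tab$converged & is.finite(tab[[col]]))
  v <- tab[[col]][ok]
  i <- ok[order(v, tab$c_kpa[ok], tab$m[ok])[1]]
  tab[i, c("c_kpa", "m", col)]
}

#' Grid-search identification of Ogden parameters
#'
#' Evaluates the combined objective over the discrete parameter space
#' `P = C x M` and returns the objective surface with its per-depth minima
#' `p_I` and the global minimizer `p_res` of the depth-averaged total
#' objective. Ties are broken toward smaller `c`, then smaller `m`.
#'
#' @param reference A [reference_set()].
#' @param c_kpa,m Grid axes. Defaults follow the full identification space
#'   (`C = 1:60` kPa, `M = 4:125`); supply a neighborhood for desk-scale
#'   runs.
#' @param eta Modulation factor.
#' @param delta_trim_mm Trim factor; defaults to the reference's.
#' @param forward Optional precomputed [forward_grid()] (reused across
#'   `eta`/trim evaluations).
#' @param ... Passed to [forward_grid()] (`N`, `n_steps`, `verbose`).
#' @return An object of class `objective_surface`: `surface` tibble
#'   (per-cell residuals and totals), `p_res`, `p_i` (per-depth minima),
#'   `eta`, `delta_trim_mm`, `failures`.
#' @export
grid_search <- function(reference, c_kpa = 1:60, m = 4:125, eta = NULL,
                        delta_trim_mm = NULL, forward = NULL, ...) {
  stopifnot(inherits(reference, "reference_set"))
  eta <- eta %||% reference$eta
  delta_trim_mm <- delta_trim_mm %||% reference$delta_trim_mm
  if (is.null(forward)) {
    forward <- forward_grid(reference, c_kpa, m, ...)
  }
  tab <- evaluate_objective(forward, reference, eta, delta_trim_mm)
  p_i <- dplyr::bind_rows(lapply(1:4, function(k) {
    a <- argmin_cell(tab, paste0("f_fu_", k))
    tibble::tibble(depth_index = k,
                   delta_i_mm = forward$delta_i_mm[k],
                   c_kpa = a$c_kpa, m = a$m,
                   min_f_fu = a[[paste0("f_fu_", k)]])
  }))
  a <- argmin_cell(tab, "f_fu_tot")
  structure(
    list(surface = tab,
         p_res = tibble::tibble(c_kpa = a$c_kpa, m = a$m,
                                min_f_fu_tot = a$f_fu_tot),
         p_i = p_i,
         eta = eta, delta_trim_mm = delta_trim_mm,
         region = reference$region,
         failures = sum(!tab$converged),
         forward = forward),
    class = "objective_surface"
  )
}

#' @export
print.objective_surface <- function(x, ...) {
  cat(sprintf(
    "<objective_surface>%s eta = %g, trim = %g mm, %d cells (%d failed)\n",
    if (!is.na(x$region)) paste0(" [", x$region, "]") else "",
    x$eta, x$delta_trim_mm, nrow(x$surface), x$failures))
  cat(sprintf("  p_res = (%g kPa, %g), min F_fu_tot = %.4g\n",
              x$p_res$c_kpa, x$p_res$m, x$p_res$min_f_fu_tot))
  invisible(x)
}

#' @export
tidy.objective_surface <- function(x, ...) x$surface

#' @export
glance.objective_surface <- function(x, ...) {
  tibble::tibble(
    region = x$region, eta = x$eta, delta_trim_mm = x$delta_trim_mm,
    c_res_kpa = x$p_res$c_kpa, m_res = x$p_res$m,
    min_f_fu_tot = x$p_res$min_f_fu_tot,
    n_cells = nrow(x$surface), n_failed = x$failures)
}

#' Contour plot of an objective surface
#'
#' @param object An `objective_surface`.
#' @param cap Values above `cap` are clipped for readable contours.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.objective_surface <- function(object, cap = 1.4, ...) {
  d <- object$surface
  d$value <- pmin(d$f_fu_tot, cap)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$c_kpa, y = .data$m)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = object$p_res, colour = "white", size = 2) +
    ggplot2::scale_fill_viridis_c(name = expression(F[fu]^{tot})) +
    ggplot2::labs(x = "c (kPa)", y = "m",
                  title = sprintf("Objective surface (eta = %g)", object$eta)) +
    ggplot2::theme_minimal()
}

# circularity (4 pi A / P^2) of the largest connected sublevel component on
# the nondimensionalized grid
sublevel_circularity <- function(tab, level = 1.5) {
  cs <- sort(unique(tab$c_kpa)); ms <- sort(unique(tab$m))
  c_max <- max(cs); m_max <- max(ms)
  inside <- matrix(FALSE, length(cs), length(ms))
  for (i in seq_len(nrow(tab))) {
    if (isTRUE(tab$converged[i]) && is.finite(tab$f_fu_tot[i]) &&
        tab$f_fu_tot[i] <= level) {
      inside[match(tab$c_kpa[i], cs), match(tab$m[i], ms)] <- TRUE
    }
  }
  if (!any(inside)) return(NA_real_)
  # connected components, 4-neighborhood
  lab <- matrix(0L, nrow(inside), ncol(inside))
  cur <- 0L
  for (i0 in seq_len(nrow(inside))) for (j0 in seq_len(ncol(inside))) {
    if (!inside[i0, j0] || lab[i0, j0] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i0, j0))
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- p[1]; j <- p[2]
      if (i < 1 || j < 1 || i > nrow(inside) || j > ncol(inside)) next
      if (!inside[i, j] || lab[i, j] > 0L) next
      lab[i, j] <- cur
      stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
    }
  }
  big <- which.max(tabulate(lab[lab > 0L]))
  comp <- lab == big
  dc <- if (length(cs) > 1) mean(diff(cs)) / c_max else 1
  dm <- if (length(ms) > 1) mean(diff(ms)) / m_max else 1
  area <- sum(comp) * dc * dm
  per <- 0
  for (i in seq_len(nrow(comp))) for (j in seq_len(ncol(comp))) {
    if (!comp[i, j]) next
    if (i == 1 || !comp[i - 1, j]) per <- per + dm
    if (i == nrow(comp) || !comp[i + 1, j]) per <- per + dm
    if (j == 1 || !comp[i, j - 1]) per <- per + dc
    if (j == ncol(comp) || !comp[i, j + 1]) per <- per + dc
  }
  4 * pi * area / per^2
}

#' Trim-factor selection for one region
#'
#' Evaluates candidate trim factors (0.1-1.2 mm) on a fixed forward grid
#' using six criteria: (1) the SD of the distances between the total
#' objective and the per-depth objectives, (2) the proportion of the
#' parameter space with total objective above 1.5, (3) the circularity of
#' the sublevel region `F_fu_tot <= 1.5` on the nondimensionalized grid,
#' (4) the mean force-to-surface residual balance (closest to 0.5 at the
#' lowest feasible candidate), and (5, 6) the relative change of the
#' resulting `c` and `m`. Criteria 1-3 target the first candidate at which
#' the series has converged to within 2% (5-6: within 1%); the selected
#' trim factor is the rounded mean of the six individual targets.
#'
#' @param reference A [reference_set()].
#' @param forward A precomputed [forward_grid()] (the expensive part; one
#'   grid serves all candidates).
#' @param candidates Candidate trim factors, mm.
#' @param eta Modulation factor.
#' @return An object of class `trim_evaluation`: `series` tibble (one row
#'   per candidate with the six criterion values), `targets` (per-criterion
#'   selected candidates, `NA` when a criterion did not converge), and
#'   `selected_mm`.
#' @export
select_trim_factor <- function(reference, forward,
                               candidates = seq(0.1, 1.2, by = 0.1),
                               eta = NULL) {
  eta <- eta %||% reference$eta
  rows <- lapply(candidates, function(dt) {
    tab <- tryCatch(evaluate_objective(forward, reference, eta, dt),
                    error = function(e) NULL)
    if (is.null(tab) || !any(tab$converged & is.finite(tab$f_fu_tot))) {
      # candidate infeasible (e.g. trim deeper than the shallowest
      # reference profile): dropped from every criterion series
      return(tibble::tibble(
        delta_trim_mm = dt, sd_dist = NA_real_, frac_above = NA_real_,
        circularity = NA_real_, balance = NA_real_, c_res = NA_real_,
        m_res = NA_real_))
    }
    ok <- tab$converged
    dist_sd <- sd(abs(as.matrix(tab[ok, paste0("f_fu_", 1:4)]) -
                        tab$f_fu_tot[ok]))
    a <- argmin_cell(tab, "f_fu_tot")
    ff_mean <- mean(as.matrix(tab[ok, paste0("f_f_", 1:4)]))
    fu_mean <- mean(as.matrix(tab[ok, paste0("f_u_", 1:4)]))
    tibble::tibble(
      delta_trim_mm = dt,
      sd_dist = dist_sd,
      frac_above = mean(tab$f_fu_tot[ok] > 1.5),
      circularity = sublevel_circularity(tab),
      balance = ff_mean / (ff_mean + fu_mean),
      c_res = a$c_kpa,
      m_res = a$m)
  })
  series <- dplyr::bind_rows(rows)
  # first candidate at which the series has stopped moving (relative change
  # within tol of the next candidate); a constant series selects the lowest
  conv_target <- function(v, tol) {
    if (all(!is.finite(v))) return(NA_real_)
    for (k in 2:length(v)) {
      if (!is.finite(v[k]) || !is.finite(v[k - 1])) next
      if (abs(v[k] - v[k - 1]) <= tol * max(abs(v[k - 1]), 1e-12)) {
        return(candidates[k - 1])
      }
    }
    NA_real_
  }
  targets <- c(
    sd_dist = conv_target(series$sd_dist, 0.02),
    frac_above = conv_target(series$frac_above, 0.02),
    circularity = conv_target(series$circularity, 0.02),
    balance = candidates[order(abs(series$balance - 0.5), candidates)[1]],
    c_res = conv_target(series$c_res, 0.01),
    m_res = conv_target(series$m_res, 0.01)
  )
  if (any(is.na(targets))) {
    rlang::warn("some trim criteria did not converge; averaging the rest")
  }
  selected <- round(mean(targets, na.rm = TRUE), 1)
  structure(
    list(series = series, targets = targets, selected_mm = selected,
         region = reference$region),
    class = "trim_evaluation"
  )
}

#' @export
print.trim_evaluation <- function(x, ...) {
  cat(sprintf("<trim_evaluation>%s selected delta_trim = %g mm\n",
              if (!is.na(x$region)) paste0(" [", x$region, "]") else "",
              x$selected_mm))
  invisible(x)
}
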