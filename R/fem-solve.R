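# Quasi-static displacement-driven solution of rigid hemispherical
# indentation into the axisymmetric Ogden cylinder. The indenter is an
# analytic sphere (radius r_t) continued by a 20 mm cylindrical wall,
# pressed frictionless into the top surface; contact is enforced by a
# penalty regularization with augmented-Lagrangian multiplier updates to a
# penetration tolerance of 1e-3 * r_t.

# 1D quadratic edge shape functions at xi for nodes at (-1, 0, +1)
edge_shape <- function(xi) {
  list(
    L = c(xi * (xi - 1) / 2, 1 - xi^2, xi * (xi + 1) / 2),
    dL = c(xi - 0.5, -2 * xi, xi + 0.5)
  )
}

# contact state at one surface Gauss point against sphere + wall
# returns gap g, outward surface normal n (from indenter into tissue)
contact_gap <- function(x, z, c_z, r_t, wall_len = 20) {
  if (z < c_z) {
    d <- sqrt(x^2 + (z - c_z)^2)
    list(g = d - r_t, n = c(x, z - c_z) / max(d, 1e-12), d = d, sphere = TRUE)
  } else if (z <= c_z + wall_len) {
    list(g = x - r_t, n = c(1, 0), d = Inf, sphere = FALSE)
  } else {
    list(g = Inf, n = c(1, 0), d = Inf, sphere = FALSE)
  }
}

# contact residual/stiffness over the top surface at indenter depth delta.
# lambda: multiplier per (edge, gp). Emits a *fixed* triplet pattern (all
# edge/GP blocks, zero-valued when inactive) so the global sparsity pattern
# can be preassembled once. Returns fc (external force vector), triplets
# for Kc, total vertical reaction, max penetration, updated tn.
contact_assemble <- function(mesh, u, delta, eps, lambda, r_t = 10) {
  nodes <- mesh$nodes
  edges <- mesh$top_edges
  H <- mesh$spec$height_mm
  c_z <- H + r_t - delta
  gp <- c(-0.9324695142031521, -0.6612093864662645, -0.2386191860831969,
          0.2386191860831969, 0.6612093864662645, 0.9324695142031521)
  gw <- c(0.1713244923791704, 0.3607615730481386, 0.4679139345726910,
          0.4679139345726910, 0.3607615730481386, 0.1713244923791704)
  ndof <- 2L * nrow(nodes)
  fc <- numeric(ndof)
  n_ent <- nrow(edges) * 6L * 9L * 4L
  ti <- tj <- integer(n_ent)
  tx <- numeric(n_ent)
  pos <- 0L
  reaction <- 0
  max_pen <- 0
  tn_out <- lambda * 0
  for (e in seq_len(nrow(edges))) {
    en <- edges[e, ]
    xr <- nodes[en, 1] + u[en, 1]
    xz <- nodes[en, 2] + u[en, 2]
    for (k in 1:6) {
      sh <- edge_shape(gp[k])
      px <- sum(sh$L * xr); pz <- sum(sh$L * xz)
      cg <- contact_gap(px, pz, c_z, r_t)
      # C1-smoothed penalty ramp: q = lambda - eps*g, smoothing half-width
      # qs (the penalty force at the penetration tolerance), removes the
      # active-set kink that makes full Newton steps chatter
      q <- lambda[e, k] - eps * cg$g
      qs <- eps * 0.01
      if (q >= qs) {
        tn <- q; dfac <- 1
      } else if (q > -qs) {
        tn <- (q + qs)^2 / (4 * qs); dfac <- (q + qs) / (2 * qs)
      } else {
        tn <- 0; dfac <- 0
      }
      tn_out[e, k] <- tn
      if (tn > 0) {
        tvx <- sum(sh$dL * xr); tvz <- sum(sh$dL * xz)
        ds <- sqrt(tvx^2 + tvz^2)
        max_pen <- max(max_pen, -cg$g)
        w <- 2 * pi * max(px, 1e-9) * ds * gw[k]
        f2 <- tn * cg$n * w
        reaction <- reaction - f2[2]
        fc[2L * en - 1L] <- fc[2L * en - 1L] + sh$L * f2[1]
        fc[2L * en] <- fc[2L * en] + sh$L * f2[2]
        # K contribution: dfac*eps n(x)n - tn (I - n(x)n)/d  (sphere curvature)
        nn <- outer(cg$n, cg$n)
        kmat <- dfac * eps * nn * w
        if (cg$sphere) kmat <- kmat - tn * (diag(2) - nn) / cg$d * w
      } else {
        kmat <- matrix(0, 2, 2)
      }
      for (a in 1:3) for (b in 1:3) {
        blk <- sh$L[a] * sh$L[b] * kmat
        ti[pos + 1:4] <- c(2L * en[a] - 1L, 2L * en[a] - 1L, 2L * en[a], 2L * en[a])
        tj[pos + 1:4] <- c(2L * en[b] - 1L, 2L * en[b], 2L * en[b] - 1L, 2L * en[b])
        tx[pos + 1:4] <- c(blk[1, 1], blk[1, 2], blk[2, 1], blk[2, 2])
        pos <- pos + 4L
      }
    }
  }
  list(fc = fc, Ki = ti, Kj = tj, Kx = tx, reaction = reaction,
       max_pen = max_pen, tn = tn_out)
}

# Precompute the fixed sparsity pattern of the free-dof tangent (element +
# contact blocks, boundary rows/columns eliminated), the map from triplet
# index to position in the CSC x-slot, and a slot for the cached CHOLMOD
# symbolic factorization. Returned as an environment so the factorization
# cache persists across Newton calls.
make_k_pattern <- function(mesh, free) {
  nodes <- mesh$nodes
  ndof <- 2L * nrow(nodes)
  u0 <- matrix(0, nrow(nodes), 2)
  asm <- fem_assemble_cpp(nodes, u0, mesh$conn - 1L, 1, 2, 1, 2L)
  con <- contact_assemble(mesh, u0, 0, 1, matrix(0, nrow(mesh$top_edges), 6))
  iall <- c(asm$Ki, con$Ki)
  jall <- c(asm$Kj, con$Kj)
  remap <- integer(ndof)
  remap[free] <- seq_along(free)
  ri <- remap[iall]
  rj <- remap[jall]
  keep <- ri > 0L & rj > 0L
  ri <- ri[keep]; rj <- rj[keep]
  nf <- length(free)
  key <- ri + (rj - 1) * as.numeric(nf)
  o <- order(key)
  grp <- cumsum(!duplicated(key[o]))
  map <- integer(length(key))
  map[o] <- grp
  K0 <- Matrix::sparseMatrix(i = ri, j = rj, x = numeric(length(ri)),
                             dims = c(nf, nf))
  # sparseMatrix orders CSC by column then row, matching the key order
  env <- new.env(parent = emptyenv())
  env$K0 <- K0
  env$map <- map
  env$keep <- keep
  env$chol <- NULL
  env
}

# factor + solve on the reduced system, reusing the symbolic factorization;
# falls back to sparse LU when the tangent is not factorizable as LDL'
solve_reduced <- function(pattern, K, rhs) {
  ch <- tryCatch({
    if (is.null(pattern$chol)) {
      pattern$chol <- Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = TRUE)
    } else {
      pattern$chol <- Matrix::update(pattern$chol,
                                     Matrix::forceSymmetric(K))
    }
    pattern$chol
  }, error = function(e) NULL)
  if (!is.null(ch)) {
    out <- tryCatch(as.numeric(Matrix::solve(ch, rhs)),
                    error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) return(out)
  }
  tryCatch(as.numeric(Matrix::solve(K, rhs)), error = function(e) NULL)
}

# gaps at current state (for multiplier updates)
contact_gaps <- function(mesh, u, delta, r_t = 10) {
  edges <- mesh$top_edges
  nodes <- mesh$nodes
  c_z <- mesh$spec$height_mm + r_t - delta
  gp <- c(-0.9324695142031521, -0.6612093864662645, -0.2386191860831969,
          0.2386191860831969, 0.6612093864662645, 0.9324695142031521)
  g <- matrix(0, nrow(edges), 6)
  for (e in seq_len(nrow(edges))) {
    en <- edges[e, ]
    xr <- nodes[en, 1] + u[en, 1]
    xz <- nodes[en, 2] + u[en, 2]
    for (k in 1:6) {
      sh <- edge_shape(gp[k])
      g[e, k] <- contact_gap(sum(sh$L * xr), sum(sh$L * xz), c_z, r_t)$g
    }
  }
  g
}

# One Newton solve at fixed indenter depth, with a backtracking line
# search (contact active-set changes make full steps overshoot).
# Returns list(ok, u, asm, con, iters).
newton_solve <- function(mesh, u, delta, cpar, eps, lambda, free,
                         pattern = NULL, rtol = 1e-6, atol = 1e-9,
                         max_iter = 25L) {
  nodes <- mesh$nodes
  conn0 <- mesh$conn - 1L
  ndof <- 2L * nrow(nodes)
  if (is.null(pattern)) pattern <- make_k_pattern(mesh, free)
  state <- function(u) {
    asm <- fem_assemble_cpp(nodes, u, conn0, cpar$c_mpa, cpar$m,
                            cpar$kappa_mpa, cpar$ngauss)
    if (!asm$ok) return(NULL)
    con <- contact_assemble(mesh, u, delta, eps, lambda)
    res <- asm$fint - con$fc
    list(asm = asm, con = con, res = res, rn = sqrt(sum(res[free]^2)))
  }
  st <- state(u)
  if (is.null(st)) return(list(ok = FALSE, why = "element inversion"))
  for (it in seq_len(max_iter)) {
    ref <- max(sqrt(sum(st$asm$fint[free]^2)), sqrt(sum(st$con$fc^2)), 1e-6)
    if (st$rn <= max(rtol * ref, atol)) {
      return(list(ok = TRUE, u = u, asm = st$asm, con = st$con, iters = it))
    }
    K <- pattern$K0
    K@x <- accum_pattern_cpp(c(st$asm$Kx, st$con$Kx)[pattern$keep],
                             pattern$map, length(K@x))
    du_f <- solve_reduced(pattern, K, -st$res[free])
    if (is.null(du_f) || any(!is.finite(du_f))) {
      return(list(ok = FALSE, why = "singular tangent"))
    }
    du <- numeric(ndof)
    du[free] <- du_f
    alpha <- 1
    accepted <- FALSE
    while (!accepted) {
      ut <- u
      ut[, 1] <- ut[, 1] + alpha * du[seq(1, ndof, 2)]
      ut[, 2] <- ut[, 2] + alpha * du[seq(2, ndof, 2)]
      st_t <- state(ut)
      if (!is.null(st_t) &&
          (st_t$rn < (1 - 0.1 * alpha) * st$rn || alpha <= 1 / 128)) {
        u <- ut
        st <- st_t
        accepted <- TRUE
      } else {
        alpha <- alpha / 2
        if (alpha < 1 / 1024) {
          return(list(ok = FALSE, why = "line search failed"))
        }
      }
    }
  }
  list(ok = FALSE, why = "no convergence")
}

#' Solve rigid hemispherical indentation of the Ogden cylinder
#'
#' Displacement-driven quasi-static solution: the rigid indenter (analytic
#' hemisphere of radius 10 mm continued by a 20 mm cylindrical wall) is
#' moved vertically downward to `delta_max_mm` in uniform steps, with
#' automatic step bisection on Newton divergence (absolute floor 0.02 mm).
#' The bottom face is fully fixed, the axis radially constrained, the
#' outer wall free; contact is frictionless (penalty + augmented-
#' Lagrangian updates to a penetration tolerance of `1e-3 * r_t`). The
#' reaction force is the total vertical contact force.
#'
#' @param mesh A [build_mesh()] result.
#' @param params An [ogden_params()] (kPa).
#' @param delta_max_mm Maximum indentation depth.
#' @param n_steps Number of uniform recording steps to `delta_max_mm`; the
#'   four equally spaced depth stations `delta_I` are steps
#'   `n_steps * (1:4) / 4`.
#' @param ngauss Gauss points per direction: 2 (default) is the standard
#'   reduced rule for 8-node serendipity elements; 3 is full integration.
#' @param penalty_factor Contact penalty stiffness in multiples of `c`.
#' @param max_augment Maximum augmented-Lagrangian updates per step.
#' @param verbose Print per-step progress.
#' @return An object of class `indentation_solution`: tibble `history`
#'   (`delta_mm`, `reaction_n`, `energy_nmm`, `max_abs_jm1`), list
#'   `profiles` of top-edge displacement tibbles per recorded step
#'   (`r_mm` initial radius, `u_r_mm`, `u_z_mm`), the four `delta_i_mm`,
#'   and solver diagnostics.
#' @export
solve_indentation <- function(mesh, params, delta_max_mm, n_steps = 24L,
                              ngauss = 2L, penalty_factor = 50,
                              max_augment = 12L, verbose = FALSE) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(params, "ogden_params"))
  assert_that(delta_max_mm > 0, "delta_max must be positive")
  nodes <- mesh$nodes
  ndof <- 2L * nrow(nodes)
  cpar <- list(c_mpa = params$c_kpa * 1e-3, m = params$m,
               kappa_mpa = params$kappa_kpa * 1e-3, ngauss = ngauss)
  # bottom face fully fixed, axis radially constrained
  fixed <- c(2L * mesh$sets$axis - 1L,
             2L * mesh$sets$bottom - 1L, 2L * mesh$sets$bottom)
  free <- setdiff(seq_len(ndof), fixed)
  r_t <- 10
  eps <- penalty_factor * cpar$c_mpa
  g_tol <- 1e-3 * r_t

  u <- matrix(0, nrow(nodes), 2)
  lambda <- matrix(0, nrow(mesh$top_edges), 6)
  pattern <- make_k_pattern(mesh, free)
  targets <- delta_max_mm * seq_len(n_steps) / n_steps
  base_step <- delta_max_mm / n_steps
  # deep bisection is cheap with warm starts; a generous absolute floor
  # avoids spurious nonconvergence of very soft materials on refined
  # meshes, independent of how coarsely the recording steps are chosen
  min_step <- min(base_step / 64, 0.02)

  hist_delta <- 0; hist_reaction <- 0; hist_energy <- 0; hist_j <- 0
  top <- mesh$sets$top
  profiles <- list(tibble::tibble(r_mm = nodes[top, 1], u_r_mm = 0, u_z_mm = 0))
  delta <- 0
  total_newton <- 0L
  u_prev <- NULL     # converged state one increment back
  d_last <- NA_real_ # size of the last successful increment
  step_cap <- Inf    # ceiling set by recent failed attempts

  for (tgt in targets) {
    step <- min(base_step, tgt - delta)
    # engage contact gently: the first increments from zero are the hard
    # ones, and failed large attempts are far costlier than extra small
    # steps (the controller doubles the step after every success)
    if (delta == 0) step <- min(step, 0.5)
    while (delta < tgt - 1e-12) {
      dtry <- min(step, tgt - delta)
      attempt <- delta + dtry
      u_save <- u
      lambda_save <- lambda
      # warm start: linear extrapolation of the last increment
      if (!is.null(u_prev) && is.finite(d_last) && d_last > 0) {
        u <- u + (u - u_prev) * (dtry / d_last)
      }
      sol <- NULL
      for (aug in seq_len(max_augment)) {
        ns <- newton_solve(mesh, u, attempt, cpar, eps, lambda, free,
                           pattern = pattern)
        if (!ns$ok) break
        total_newton <- total_newton + ns$iters
        sol <- ns
        u <- ns$u
        g <- contact_gaps(mesh, u, attempt)
        pen <- max(0, -min(g))
        lambda <- pmax(lambda - eps * g, 0)  # keeps matrix shape
        if (pen <= g_tol) break
      }
      if (is.null(sol) || !ns$ok) {
        u <- u_save          # roll back the failed attempt entirely
        lambda <- lambda_save
        u_prev <- NULL       # and drop the extrapolation basis
        step_cap <- dtry / 2 # remember how big an attempt just failed
        step <- dtry / 2
        if (step < min_step) {
          rlang::abort(sprintf(
            "indentation solve did not converge (c = %g kPa, m = %g, delta = %g mm)",
            params$c_kpa, params$m, attempt), class = "indentfe_nonconvergence")
        }
        next
      }
      u_prev <- u_save
      d_last <- dtry
      step_cap <- step_cap * 1.3   # slow recovery after failures
      delta <- attempt
      if (verbose) {
        message(sprintf("  delta %6.3f mm  f = %8.4f N  augs %d  iters %d",
                        delta, sol$con$reaction, aug, total_newton))
      }
      step <- min(base_step, step * 2, step_cap)
      # failed large attempts cost far more than extra small successes
      # while the contact is still establishing itself
      if (delta < 2) step <- min(step, 0.5)
    }
    hist_delta <- c(hist_delta, delta)
    hist_reaction <- c(hist_reaction, sol$con$reaction)
    hist_energy <- c(hist_energy, sol$asm$energy)
    hist_j <- c(hist_j, sol$asm$max_abs_jm1)
    profiles[[length(profiles) + 1L]] <-
      tibble::tibble(r_mm = nodes[top, 1], u_r_mm = u[top, 1], u_z_mm = u[top, 2])
  }

  structure(
    list(
      params = params,
      mesh_N = mesh$spec$N,
      history = tibble::tibble(
        delta_mm = hist_delta, reaction_n = hist_reaction,
        energy_nmm = hist_energy, max_abs_jm1 = hist_j),
      profiles = profiles,
      delta_i_mm = delta_max_mm * (1:4) / 4,
      n_steps = n_steps,
      total_newton = total_newton
    ),
    class = "indentation_solution"
  )
}

#' @export
print.indentation_solution <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf(
    "<indentation_solution> c = %g kPa, m = %g, N = %d: delta = %g mm, f = %.4g N\n",
    x$params$c_kpa, x$params$m, x$mesh_N,
    x$history$delta_mm[n], x$history$reaction_n[n]))
  invisible(x)
}

#' Reaction force at a recorded indentation depth
#'
#' @param solution An [solve_indentation()] result.
#' @param delta_mm Recorded depth (must coincide with a recording step).
#' @return Reaction force in N.
#' @export
reaction_at <- function(solution, delta_mm) {
  i <- which(abs(solution$history$delta_mm - delta_mm) < 1e-9)
  assert_that(length(i) == 1L, "depth was not a recording step")
  solution$history$reaction_n[i]
}

#' Top-surface displacement profile at a recorded depth
#'
#' Vertical displacements of the top outer-edge nodes (the quantities a
#' surface-ranging sensor can observe), ordered by initial radius.
#'
#' @param solution An [solve_indentation()] result.
#' @param delta_mm Recorded depth.
#' @return Tibble `r_mm` (initial radius), `u_mm` (vertical displacement,
#'   negative downward).
#' @export
surface_profile <- function(solution, delta_mm) {
  i <- which(abs(solution$history$delta_mm - delta_mm) < 1e-9)
  assert_that(length(i) == 1L, "depth was not a recording step")
  p <- solution$profiles[[i]]
  tibble::tibble(r_mm = p$r_mm, u_mm = p$u_z_mm)
}

#' @export
autoplot.indentation_solution <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$delta_mm, y = .data$reaction_n)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(delta ~ "(mm)"), y = "reaction force (N)",
      title = sprintf("Indentation response, c = %g kPa, m = %g",
                      object$params$c_kpa, object$params$m)) +
    ggplot2::theme_minimal()
}

#' Mesh convergence of the forward indentation model
#'
#' Solves the indentation at several mesh refinement factors and reports
#' relative errors versus a fine reference mesh: the force error
#' `E_F(N) = |F(N) - F(Nref)| / F(Nref) * 100` at the evaluation depth and
#' the surface error `E_u(N)`, the mean over top-edge nodes (initial radius
#' at least the tip radius) of `|u_i(N) - u_i(Nref)| / |u_i(Nref)| * 100`,
#' with the reference displacements interpolated to the coarse node radii
#' by a monotone cubic.
#'
#' @param N_values Refinement factors to evaluate.
#' @param reference_N Reference refinement (error 0 by construction).
#' @param materials List of [ogden_params()] sets.
#' @param delta_mm Evaluation depth.
#' @param n_steps Load steps per solve.
#' @param verbose Print progress.
#' @return A tibble of class `convergence_report`: one row per
#'   (material, N) with `c_kpa`, `m`, `N`, `e_f_pct`, `e_u_pct`,
#'   `reaction_n`.
#' @export
mesh_convergence <- function(N_values = c(1, 2, 3),
                             reference_N = 6,
                             materials = list(
                               ogden_params(1, 4),
                               ogden_params(45, 30),
                               ogden_params(140, 60)),
                             delta_mm = 20, n_steps = 20L,
                             verbose = FALSE) {
  r_t <- 10
  rows <- list()
  for (mat in materials) {
    ref <- solve_indentation(build_mesh(mesh_spec(N = reference_N)), mat,
                             delta_mm, n_steps = n_steps)
    pref <- surface_profile(ref, delta_mm)
    f_ref <- reaction_at(ref, delta_mm)
    interp <- splinefun(pref$r_mm, pref$u_mm, method = "monoH.FC")
    for (N in N_values) {
      if (N == reference_N) {
        sol <- ref
      } else {
        sol <- solve_indentation(build_mesh(mesh_spec(N = N)), mat,
                                 delta_mm, n_steps = n_steps)
      }
      f_n <- reaction_at(sol, delta_mm)
      pn <- surface_profile(sol, delta_mm)
      u_r_all <- interp(pn$r_mm)
      # relative displacement errors are meaningful only where the
      # reference displacement is numerically nonzero: the profile crosses
      # zero between the concave zone and the outer uplift, and nodes at
      # that crossing would dominate the mean with unbounded ratios
      keep <- pn$r_mm >= r_t & abs(u_r_all) >= 0.01 * max(abs(u_r_all))
      u_n <- pn$u_mm[keep]
      u_r <- u_r_all[keep]
      e_u <- mean(abs((u_n - u_r) / u_r)) * 100
      e_f <- abs((f_n - f_ref) / f_ref) * 100
      if (verbose) {
        message(sprintf("c=%g m=%g N=%d: E_F=%.3f%% E_u=%.3f%%",
                        mat$c_kpa, mat$m, N, e_f, e_u))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        c_kpa = mat$c_kpa, m = mat$m, N = N,
        e_f_pct = e_f, e_u_pct = e_u, reaction_n = f_n)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("convergence_report", class(out))
  out
}

#' Plot a mesh-convergence report
#'
#' @param object A [mesh_convergence()] report.
#' @param target_pct Convergence target line.
#' @param ... Unused.
#' @return A ggplot of the force and surface errors against the refinement
#'   factor.
#' @export
autoplot.convergence_report <- function(object, target_pct = 1, ...) {
  d <- tidyr::pivot_longer(object, c("e_f_pct", "e_u_pct"),
                           names_to = "error", values_to = "pct")
  d$error <- ifelse(d$error == "e_f_pct", "indentation force",
                    "surface displacement")
  d$material <- sprintf("c = %g kPa, m = %g", d$c_kpa, d$m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$N, y = .data$pct,
                                  colour = .data$material)) +
    ggplot2::geom_hline(yintercept = target_pct, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~error) +
    ggplot2::labs(x = "mesh refinement factor N", y = "relative error (%)") +
    ggplot2::theme_minimal()
}
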