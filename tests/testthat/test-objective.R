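test_that("force residual is the squared relative force error", {
  expect_equal(force_residual(5, 5), 0)
  expect_equal(force_residual(10, 5), 1)
  expect_equal(force_residual(9.0, 8.53), ((9 - 8.53) / 8.53)^2)
  expect_equal(force_residual(9.0, 8.53), 0.003036, tolerance = 1e-3)
  expect_error(force_residual(1, 0), "nonzero")
})

test_that("node weights form the inverse-radius convex combination", {
  expect_equal(node_weights(17), 1)
  expect_equal(node_weights(c(10, 20)), c(2 / 3, 1 / 3))
  expect_equal(node_weights(rep(4, 7)), rep(1 / 7, 7))
  for (seed in 1:5) {
    r <- with_seed_helper(seed, runif(20, 1, 110))
    w <- node_weights(r)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
  }
  expect_error(node_weights(numeric(0)), "empty")
})

test_that("surface residual measures weighted relative deviations in the trim window", {
  msd <- as_mean_surface("R3", 25)
  f <- compose_full_profile(msd)
  r <- seq(11, 55, by = 2)
  sim_exact <- tibble::tibble(r_mm = r, u_mm = f(r))
  expect_equal(surface_residual(sim_exact, msd, 0.5), 0, tolerance = 1e-20)
  # convex-combination weighting: a uniform 10% error gives exactly 0.01
  sim_off <- tibble::tibble(r_mm = r, u_mm = 1.1 * f(r))
  expect_equal(surface_residual(sim_off, msd, 0.5, normalization = "sum"),
               0.01, tolerance = 1e-10)
  # default norm weighting rescales the same deviation by ||1/r||-relative
  # factor sum(1/r)/||1/r||
  keep <- r >= msd$x_min_mm & r <= x_trim_from_delta(msd, 0.5)
  scale_fac <- sum(1 / r[keep]) / sqrt(sum(1 / r[keep]^2))
  expect_equal(surface_residual(sim_off, msd, 0.5), 0.01 * scale_fac,
               tolerance = 1e-10)
  # trim bound: nodes outside x_trim do not contribute
  xt <- x_trim_from_delta(msd, 0.5)
  sim_tail <- sim_exact
  sim_tail$u_mm[sim_tail$r_mm > xt] <- sim_tail$u_mm[sim_tail$r_mm > xt] + 5
  expect_equal(surface_residual(sim_tail, msd, 0.5), 0, tolerance = 1e-20)
})

test_that("combined and total objectives follow their definitions", {
  expect_equal(combined_objective(0.7, 0.2, 1), 0.7)
  expect_equal(combined_objective(0.7, 0.2, 0), 0.2)
  expect_equal(combined_objective(0.2, 0.4, 0.5), 0.3)
  # exact linearity in eta
  ff <- 0.31; fu <- 0.12
  etas <- seq(0, 1, by = 0.1)
  vals <- combined_objective(ff, fu, etas)
  expect_equal(vals, fu + etas * (ff - fu), tolerance = 1e-15)
  expect_error(combined_objective(1, 1, 1.2), "eta")

  expect_equal(total_objective(rep(0.3, 4)), 0.3)
  expect_equal(total_objective(c(0.06, 0.27, 0.37, 0.42)), 0.28)
  base <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(total_objective(base + c(0.4, 0, 0, 0)),
               total_objective(base) + 0.1)
  expect_error(total_objective(c(0.1, 0.2)), "four")
})

test_that("reference sets bundle the regional tables coherently", {
  rs <- reference_set("R3")
  expect_equal(rs$delta_i_mm, c(6.25, 12.5, 18.75, 25))
  expect_equal(rs$delta_max_star_mm, 25)
  expect_equal(rs$delta_trim_mm, 0.5)
  expect_equal(rs$f_star_n, c(1.12, 2.92, 5.39, 8.53))
  # four equally spaced depths with the last equal to delta_max*
  d <- rs$delta_i_mm
  expect_equal(diff(d), rep(d[1], 3))
})

test_that("grid search recovers planted parameters from a synthetic reference", {
  ref <- synthetic_reference(truth_solution(), delta_trim_mm = 0.3)
  gs <- grid_search(ref, forward = truth_forward_grid())
  expect_equal(gs$p_res$c_kpa, 10)
  expect_equal(gs$p_res$m, 20)
  expect_lt(gs$p_res$min_f_fu_tot, 1e-10)
  # per-depth minima also sit at the planted cell for a noiseless reference
  expect_true(all(gs$p_i$c_kpa == 10))
  expect_true(all(gs$p_i$m == 20))
  # eta extremes still minimize at the planted cell (residuals vanish there)
  gs0 <- grid_search(ref, eta = 0, forward = gs$forward)
  gs1 <- grid_search(ref, eta = 1, forward = gs$forward)
  expect_equal(c(gs0$p_res$c_kpa, gs0$p_res$m), c(10, 20))
  expect_equal(c(gs1$p_res$c_kpa, gs1$p_res$m), c(10, 20))
})

test_that("argmin tie-breaking is lexicographic in (c, m)", {
  tab <- tibble::tibble(
    c_kpa = c(2, 1, 1), m = c(4, 6, 5),
    converged = TRUE, val = c(0.5, 0.5, 0.5))
  a <- indentfe:::argmin_cell(tab, "val")
  expect_equal(c(a$c_kpa, a$m), c(1, 5))
})

test_that("sublevel circularity is exact for simple shapes", {
  # a full rectangle of cells: circularity of the covered rectangle
  tab <- tidyr::expand_grid(c_kpa = 1:10, m = 1:10)
  tab$converged <- TRUE
  tab$f_fu_tot <- 0.1
  circ <- indentfe:::sublevel_circularity(tab)
  # nondimensional grid covers [..] with dc = dm; area ~ 1, perimeter ~ 4
  expect_equal(circ, 4 * pi * (1 * 1) / 16, tolerance = 0.3)
  # a single interior cell is more circular than an elongated strip
  strip <- tab
  strip$f_fu_tot <- ifelse(strip$m == 5, 0.1, 10)
  blob <- tab
  blob$f_fu_tot <- ifelse(blob$m %in% 4:6 & blob$c_kpa %in% 4:6, 0.1, 10)
  expect_gt(indentfe:::sublevel_circularity(blob),
            indentfe:::sublevel_circularity(strip))
})

test_that("trim evaluation selects the lowest candidate for degenerate surfaces", {
  ref <- synthetic_reference(truth_solution(), delta_trim_mm = 0.3)
  te <- select_trim_factor(ref, truth_forward_grid(),
                           candidates = seq(0.1, 0.5, by = 0.1))
  expect_s3_class(te, "trim_evaluation")
  expect_equal(nrow(te$series), 5L)
  # the planted-cell minimizer is trim-invariant, so the resulting-c and
  # resulting-m criteria converge at the lowest comparison
  expect_equal(unname(te$targets["c_res"]), 0.1)
  expect_equal(unname(te$targets["m_res"]), 0.1)
  expect_true(te$selected_mm >= 0.1 && te$selected_mm <= 0.5)
})
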