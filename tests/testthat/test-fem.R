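test_that("mesh construction honors the stated layout", {
  m <- build_mesh(mesh_spec(N = 3))
  expect_equal(nrow(m$conn), 450L)
  expect_equal(m$spec$n_radial, 30L)
  expect_equal(m$spec$n_axial, 15L)
  expect_equal(max(m$nodes[, 1]), 110, tolerance = 1e-9)
  expect_equal(max(m$nodes[, 2]), 110, tolerance = 1e-9)
  # corner radial widths partition the radius exactly
  rb <- indentfe:::graded_breaks(110, 30, 1.1)
  expect_equal(sum(diff(rb)), 110, tolerance = 1e-9)
  expect_equal(diff(rb)[30] / diff(rb)[1], 1.1, tolerance = 1e-9)
  # unit bias gives uniform spacing
  rb1 <- indentfe:::graded_breaks(110, 10, 1)
  expect_true(all(abs(diff(rb1) - 11) < 1e-12))
  # node sets
  expect_true(all(m$nodes[m$sets$axis, 1] == 0))
  expect_true(all(m$nodes[m$sets$bottom, 2] == 0))
  expect_true(all(m$nodes[m$sets$top, 2] == 110))
})

test_that("Ogden stress matches analytic and finite-difference oracles", {
  p <- ogden_params(7, 12)
  # stress-free reference
  expect_lt(max(abs(ogden_stress(p, diag(3))$sigma)), 1e-12)
  # pure volumetric response: pressure kappa ln(J) / J
  J <- 1.05
  sv <- ogden_stress(p, J^(1 / 3) * diag(3))
  expect_equal(sv$sigma[1, 1], p$kappa_kpa * log(J) / J, tolerance = 1e-9)
  expect_lt(abs(sv$sigma[1, 1] - sv$sigma[2, 2]), 1e-9)
  # incompressible uniaxial stretch vs finite difference of the energy
  for (lam in c(0.8, 1.3, 1.7)) {
    Fm <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
    s <- ogden_stress(p, Fm)
    h <- 1e-6
    psi <- function(l) ogden_stress(p, diag(c(l, 1 / sqrt(l), 1 / sqrt(l))))$psi
    oracle <- lam * (psi(lam + h) - psi(lam - h)) / (2 * h)
    expect_equal(s$sigma[1, 1] - s$sigma[2, 2], oracle, tolerance = 1e-5)
  }
  expect_error(ogden_stress(p, -diag(3)), "positive")
})

test_that("small-strain moduli follow from the parameter set", {
  p <- ogden_params(7, 12)
  mod <- small_strain_moduli(p)
  # first-order Ogden in this form has mu = c/2 independent of m
  expect_equal(mod$mu_kpa, 3.5, tolerance = 1e-4)
  expect_equal(small_strain_moduli(ogden_params(7, 40))$mu_kpa, 3.5,
               tolerance = 1e-3)
  expect_gt(mod$nu, 0.499)
})

test_that("assembled internal forces satisfy homogeneous patch states", {
  mesh <- build_mesh(mesh_spec(N = 2))
  nodes <- mesh$nodes
  p <- ogden_params(7, 12)
  lz <- 0.7
  lr <- 1 / sqrt(lz)
  u <- cbind((lr - 1) * nodes[, 1], (lz - 1) * nodes[, 2])
  asm <- indentfe:::fem_assemble_cpp(nodes, u, mesh$conn - 1L,
                                     7e-3, 12, 14, 3L)
  expect_true(asm$ok)
  s <- ogden_stress(p, diag(c(lr, lz, lr)))
  # top-face vertical force equals sigma_zz times the current area
  expect_equal(sum(asm$fint[2 * mesh$sets$top]),
               s$sigma[2, 2] * 1e-3 * pi * (110 * lr)^2, tolerance = 1e-6)
  # interior nodes are in equilibrium under the homogeneous stress
  surface <- unique(c(mesh$sets$top, mesh$sets$bottom, mesh$sets$axis,
                      which(abs(nodes[, 1] - 110) < 1e-9)))
  interior <- setdiff(seq_len(nrow(nodes)), surface)
  expect_lt(max(abs(asm$fint[c(2 * interior, 2 * interior - 1L)])), 1e-6)
})

test_that("assembled tangent is the derivative of the internal force", {
  mesh <- build_mesh(mesh_spec(N = 1))
  nodes <- mesh$nodes
  ndof <- 2L * nrow(nodes)
  u <- matrix(with_seed_helper(11, rnorm(ndof, sd = 0.15)), nrow(nodes), 2)
  asm <- indentfe:::fem_assemble_cpp(nodes, u, mesh$conn - 1L, 7e-3, 12, 14, 3L)
  expect_true(asm$ok)
  K <- Matrix::sparseMatrix(i = asm$Ki, j = asm$Kj, x = asm$Kx,
                            dims = c(ndof, ndof))
  h <- 1e-6
  for (dof in with_seed_helper(12, sample(ndof, 4))) {
    node <- ceiling(dof / 2)
    compo <- 2L - dof %% 2L
    up <- u; up[node, compo] <- up[node, compo] + h
    um <- u; um[node, compo] <- um[node, compo] - h
    fd <- (indentfe:::fem_assemble_cpp(nodes, up, mesh$conn - 1L, 7e-3, 12, 14, 3L)$fint -
           indentfe:::fem_assemble_cpp(nodes, um, mesh$conn - 1L, 7e-3, 12, 14, 3L)$fint) / (2 * h)
    expect_lt(max(abs(fd - as.numeric(K[, dof]))) / max(abs(fd)), 1e-6)
  }
})

test_that("indentation solution satisfies contact and energy invariants", {
  sol <- small_solution()
  h <- sol$history
  # zero depth, zero reaction; monotone non-decreasing reaction
  expect_equal(h$reaction_n[1], 0)
  expect_true(all(diff(h$reaction_n) > -1e-8))
  # near-incompressibility at every recorded state
  expect_lt(max(h$max_abs_jm1), 0.01)
  # energy consistency: dW/d(delta) matches the mean reaction (trapezoid),
  # evaluated where the force carries signal (a relative check against the
  # near-zero toe forces has no meaningful denominator)
  dW <- diff(h$energy_nmm) / diff(h$delta_mm)
  fmid <- (head(h$reaction_n, -1) + tail(h$reaction_n, -1)) / 2
  keep <- fmid >= 0.05 * max(fmid)
  expect_lt(max(abs(dW[keep] - fmid[keep]) / fmid[keep]), 0.02)
  # contact kinematics: node nearest the contact edge moves downward and
  # the deformed zone is monotone away from the indenter
  pr <- surface_profile(sol, 8)
  inner <- pr[pr$r_mm >= 10 & pr$r_mm <= 40, ]
  expect_lt(inner$u_mm[1], 0)
  expect_true(all(diff(abs(inner$u_mm)) < 1e-6))
})

test_that("reaction force scales exactly with c at fixed depth", {
  mesh <- build_mesh(mesh_spec(N = 1))
  s1 <- solve_indentation(mesh, ogden_params(5, 10), 6, n_steps = 4)
  s2 <- solve_indentation(mesh, ogden_params(15, 10), 6, n_steps = 4)
  f1 <- s1$history$reaction_n
  f2 <- s2$history$reaction_n
  expect_equal(f2[-1] / f1[-1], rep(3, length(f1) - 1L), tolerance = 1e-6)
  # displacement fields coincide (material linearity in c)
  p1 <- surface_profile(s1, 6)
  p2 <- surface_profile(s2, 6)
  expect_equal(p1$u_mm, p2$u_mm, tolerance = 1e-5)
})

test_that("mesh convergence errors vanish at the reference and are computed consistently", {
  # identity of the error formula against a brute-force relative difference
  f_n <- 9.41; f_ref <- 9.62
  e_f <- abs((f_n - f_ref) / f_ref) * 100
  expect_equal(e_f, abs(f_n - f_ref) / abs(f_ref) * 100, tolerance = 1e-12)
  # a tiny convergence run at coarse meshes: reference row must be exactly 0
  rep_ <- mesh_convergence(N_values = c(1, 2), reference_N = 2,
                           materials = list(ogden_params(45, 30)),
                           delta_mm = 6, n_steps = 4L)
  ref_row <- rep_[rep_$N == 2, ]
  expect_equal(ref_row$e_f_pct, 0)
  expect_equal(ref_row$e_u_pct, 0)
  expect_gt(rep_[rep_$N == 1, ]$e_f_pct, 0)
})
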