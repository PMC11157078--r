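# Shared fixtures. Forward solves are memoized per session so independent
# tests can share the same small solutions.

fixture_env <- new.env(parent = emptyenv())

# internal helpers exercised directly in tests
poly_eval <- indentfe:::poly_eval
pick_plane_root <- indentfe:::pick_plane_root

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# small forward solution used by several contact/profile tests
small_solution <- function() {
  cached("sol_n2_d8", {
    solve_indentation(build_mesh(mesh_spec(N = 2)), ogden_params(7, 12),
                      8, n_steps = 12)
  })
}

# ground-truth solve shared by the parameter-recovery and closure tests
truth_solution <- function() {
  cached("truth_n1", {
    solve_indentation(build_mesh(mesh_spec(N = 1)), ogden_params(10, 20),
                      10, n_steps = 4)
  })
}

# forward sweep of the 3 x 3 recovery grid around the planted optimum
truth_forward_grid <- function() {
  cached("fw_n1", {
    ref <- synthetic_reference(truth_solution(), delta_trim_mm = 0.3)
    forward_grid(ref, c_kpa = c(8, 10, 12), m = c(15, 20, 25),
                 N = 1, n_steps = 4)
  })
}

# noiseless synthetic ramp from a stored region fit
synthetic_ramp <- function(region = "R3", n = 200, sd = 0, seed = 1) {
  fit <- as_polyfit(region)
  delta <- seq(0, fit$delta_max_mm, length.out = n)
  force <- evaluate_fit(fit, delta)
  if (sd > 0) {
    force <- force + with_seed_helper(seed, rnorm(n, sd = sd))
  }
  tibble::tibble(delta_mm = delta, force_n = force)
}

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
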