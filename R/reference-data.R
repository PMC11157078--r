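#' Region-mean force-displacement reference fits
#'
#' Bundled reference dataset of through-origin polynomial fits to the mean
#' indenter force-displacement response of six abdominal measurement regions,
#' each recorded with fully relaxed (`R1`-`R6`) and controlled activated
#' (`A1`-`A6`) trunk musculature. Each fit is valid on `0 <= delta <= delta_max`
#' and stored with coefficients in descending powers (the constant term is
#' zero: all curves pass through the origin).
#'
#' @return A tibble with one row per region: `region`, `delta_max_mm`,
#'   `f_max_n`, `degree`, `coefficients` (list column, descending powers,
#'   constant term included), and `rmse` (goodness of fit as reported).
#' @seealso [as_polyfit()] to turn a row into a fit object usable with
#'   [evaluate_fit()] and [segment_stiffness()].
#' @export
#' @examples
#' fits <- reference_force_fits()
#' f_r3 <- as_polyfit(fits[fits$region == "R3", ])
#' evaluate_fit(f_r3, 30) # force in N at full stroke
reference_force_fits <- function() {
  tibble::tibble(
    region = c("R1", "R2", "R3", "R4", "R5", "R6",
               "A1", "A2", "A3", "A4", "A5", "A6"),
    delta_max_mm = c(25, 30, 30, 30, 25, 20, 20, 25, 25, 25, 24, 14),
    f_max_n = c(11.85, 13.33, 11.52, 10.33, 11.41, 32.25,
                20.94, 29.51, 27.01, 22.44, 23.86, 55.98),
    degree = c(2L, 4L, 2L, 2L, 4L, 4L, 2L, 5L, 5L, 3L, 2L, 4L),
    coefficients = list(
      c(8.684e-03, 2.462e-01, 0),
      c(-2.937e-06, 2.590e-04, 2.479e-03, 2.163e-01, 0),
      c(8.604e-03, 1.260e-01, 0),
      c(5.279e-03, 1.859e-01, 0),
      c(5.359e-06, 1.710e-04, 3.677e-03, 1.740e-01, 0),
      c(-2.765e-05, 2.665e-03, 2.231e-02, 3.214e-01, 0),
      c(3.456e-02, 3.556e-01, 0),
      c(-1.119e-05, -6.415e-04, 4.969e-02, 5.176e-02, 4.619e-01, 0),
      c(9.067e-06, -5.547e-04, 1.047e-02, -2.882e-02, 3.835e-01, 0),
      c(-3.641e-04, 2.890e-02, 4.072e-01, 0),
      c(2.864e-02, 3.068e-01, 0),
      c(-3.118e-04, -3.885e-03, 3.465e-01, 7.624e-01, 0)
    ),
    rmse = c(1.256, 0.963, 0.512, 0.660, 1.025, 2.639,
             2.913, 3.320, 3.922, 4.682, 4.037, 10.959)
  )
}

#' Region-mean surface-displacement reference profiles
#'
#' Bundled reference dataset of cubic fits `u(x)` to the mean vertical skin
#' surface displacement around the indenter tip, per measurement region and
#' discrete indentation depth `delta_I` (four equally spaced depths per
#' region, the largest being the region's `delta_max*`). `x` is the radial
#' distance from the indenter axis in mm; displacements are measured along
#' the negative z-axis relative to the undeformed reference plane (the
#' stored cubics evaluate to negative values). Each cubic is valid on
#' `x_min <= x <= x_max`, where `x_min` is the intersection with the
#' indenter tip profile and `x_max` the intersection with the reference
#' plane. `f_star_n` is the mean indentation force at `delta_I` from the
#' region's force fit.
#'
#' @return A tibble with columns `region`, `delta_i_mm`, `f_star_n`,
#'   `x_min_mm`, `x_max_mm`, and `u1`..`u4` (cubic coefficients in
#'   descending powers, mm).
#' @seealso [as_mean_surface()], [compose_full_profile()]
#' @export
reference_surface_profiles <- function() {
  x <- c(
    # region, delta_I, f*, x_min, x_max, u1, u2, u3, u4
    "R1",  5.00,  1.45, 6.089, 42.859, -1.065e-04,  6.927e-03, -3.190e-02,  -2.971,
    "R1", 10.00,  3.33, 7.831, 53.080, -4.762e-05,  3.425e-03,  8.567e-02,  -7.078,
    "R1", 15.00,  5.65, 8.837, 62.945, -4.873e-05,  4.178e-03,  1.030e-01, -10.890,
    "R1", 20.00,  8.40, 9.671, 66.729, -6.188e-05,  5.926e-03,  8.836e-02, -13.900,
    "R2",  6.25,  1.51, 7.342, 37.005, -1.993e-04,  1.256e-02, -1.166e-01,  -2.782,
    "R2", 12.50,  5.53, 8.943, 45.946, -1.246e-04,  8.224e-03,  6.108e-02,  -8.087,
    "R2", 18.75,  6.27, 9.756, 57.187, -5.454e-05,  3.227e-03,  2.287e-01, -13.430,
    "R2", 25.00,  9.86, 10.000, 65.213, -5.666e-05, 4.188e-03,  2.368e-01, -17.540,
    "R3",  6.25,  1.12, 7.566, 35.484, -2.180e-04,  1.351e-02, -1.365e-01,  -2.433,
    "R3", 12.50,  2.92, 9.293, 42.561, -1.745e-04,  1.119e-02,  5.990e-03,  -7.075,
    "R3", 18.75,  5.39, 9.942, 52.568, -6.188e-05,  3.089e-03,  2.467e-01, -12.520,
    "R3", 25.00,  8.53, 10.000, 60.609, -6.175e-05, 4.191e-03,  2.418e-01, -16.310,
    "R4",  6.25,  1.37, 7.348, 36.761, -1.688e-04,  1.022e-02, -6.487e-02,  -3.037,
    "R4", 12.50,  3.15, 9.026, 49.639, -3.117e-05,  3.522e-04,  2.401e-01,  -8.972,
    "R4", 18.75,  5.34, 9.831, 61.055, -1.742e-05, -5.439e-04,  3.221e-01, -13.670,
    "R4", 25.00,  7.94, 10.000, 67.845, -1.813e-05, -4.167e-04, 3.827e-01, -18.390,
    "R5",  6.25,  1.28, 7.331, 39.196, -1.194e-04,  7.065e-03, -8.779e-03,  -3.318,
    "R5", 12.50,  3.21, 8.955, 43.200, -1.068e-04,  5.409e-03,  1.698e-01,  -8.818,
    "R5", 18.75,  6.34, 9.697, 52.244, -4.996e-05,  1.204e-03,  3.545e-01, -14.680,
    "R5", 25.00, 11.41, 9.990, 61.790, -5.988e-05,  3.226e-03,  3.379e-01, -19.070,
    "R6",  4.00,  1.81, 6.811, 43.314,  6.690e-07, -4.281e-04,  5.611e-02,  -1.682,
    "R6",  8.00,  5.25, 8.518, 45.484, -4.420e-05,  2.257e-03,  7.747e-02,  -4.033,
    "R6", 12.00, 11.10, 9.272, 51.617,  2.646e-07, -2.121e-03,  2.639e-01,  -8.007,
    "R6", 16.00, 19.96, 9.865, 57.954,  8.678e-06, -3.241e-03,  3.435e-01, -10.710,
    "A1",  4.00,  1.98, 6.425, 45.758, -7.288e-06,  1.786e-04,  5.058e-02,  -1.990,
    "A1",  8.00,  5.06, 8.082, 45.302, -6.090e-05,  3.765e-03,  5.473e-02,  -4.543,
    "A1", 12.00,  9.24, 8.921, 49.949, -8.825e-05,  6.103e-03,  6.618e-02,  -3.340,
    "A1", 16.00, 14.54, 9.463, 55.936, -5.966e-05,  4.297e-03,  1.412e-01, -10.900,
    "A2",  5.00,  3.52, 7.095, 46.183, -1.724e-05,  5.926e-04,  6.401e-02,  -2.522,
    "A2", 10.00,  9.04, 8.513, 50.939, -3.940e-05,  2.501e-03,  9.710e-02,  -6.230,
    "A2", 15.00, 15.84, 9.315, 57.370, -4.751e-05,  3.453e-03,  1.354e-01, -10.160,
    "A2", 20.00, 23.02, 9.878, 65.679, -3.791e-05,  2.684e-03,  1.961e-01, -13.720,
    "A3",  5.00,  2.19, 7.553, 39.789,  1.582e-06, -3.823e-04,  6.318e-02,  -2.008,
    "A3", 10.00,  6.77, 9.309, 47.862, -2.645e-05,  1.298e-03,  9.510e-02,  -4.625,
    "A3", 15.00, 13.42, 9.795, 56.835, -2.952e-05,  1.614e-03,  1.561e-01,  -8.663,
    "A3", 20.00, 20.12, 10.000, 65.710, -2.590e-05, 1.704e-03,  1.772e-01, -11.650,
    "A4",  5.00,  2.74, 7.252, 49.359,  5.653e-06, -9.252e-04,  8.103e-02,  -2.425,
    "A4", 10.00,  6.66, 8.761, 49.564, -8.992e-06, -9.275e-04,  1.988e-01,  -6.479,
    "A4", 15.00, 11.44, 9.584, 57.680, -7.473e-06, -1.211e-03,  2.744e-01, -10.360,
    "A4", 20.00, 16.80, 9.981, 63.514, -1.605e-05, -1.236e-04,  2.837e-01, -13.410,
    "A5",  5.00,  2.25, 6.772, 47.663,  7.959e-06, -1.075e-03,  9.514e-02,  -2.954,
    "A5", 10.00,  5.93, 8.856, 53.956,  2.450e-05, -3.237e-03,  2.213e-01,  -6.363,
    "A5", 15.00, 11.04, 9.616, 54.403,  1.310e-05, -3.276e-03,  3.356e-01, -10.670,
    "A5", 20.00, 17.59, 9.969, 59.772,  7.236e-06, -3.051e-03,  3.979e-01, -14.430,
    "A6",  3.25,  5.97, 6.440, 52.595,  1.001e-05, -9.623e-04,  4.477e-02,  -1.149,
    "A6",  6.50, 17.97, 8.652, 54.386,  3.466e-05, -3.406e-03,  1.263e-01,  -2.373,
    "A6",  9.75, 33.95, 9.422, 61.089,  3.140e-05, -3.384e-03,  1.605e-01,  -4.337,
    "A6", 13.00, 51.03, 9.817, 67.835,  3.628e-05, -4.454e-03,  2.358e-01,  -6.824
  )
  m <- matrix(x, ncol = 9, byrow = TRUE)
  tibble::tibble(
    region = m[, 1],
    delta_i_mm = as.numeric(m[, 2]),
    f_star_n = as.numeric(m[, 3]),
    x_min_mm = as.numeric(m[, 4]),
    x_max_mm = as.numeric(m[, 5]),
    u1 = as.numeric(m[, 6]),
    u2 = as.numeric(m[, 7]),
    u3 = as.numeric(m[, 8]),
    u4 = as.numeric(m[, 9])
  )
}

#' Identified Ogden parameter sets per region
#'
#' Bundled reference dataset of the first-order Ogden material parameter sets
#' `p_res = (c, m)` identified per measurement region by the inverse
#' finite-element grid search (modulation factor eta = 0.5), together with
#' the per-depth minimizer ranges `p_I`, the trim factor used, and the
#' simulated reaction force at the region's maximum indentation depth.
#'
#' @return A tibble with columns `region`, `delta_max_star_mm`,
#'   `delta_trim_mm`, `f_sim_n`, `c_kpa`, `m`, `c_lo_kpa`, `c_hi_kpa`,
#'   `m_lo`, `m_hi`, `min_f_fu_tot`.
#' @export
identified_parameters <- function() {
  tibble::tribble(
    ~region, ~delta_max_star_mm, ~delta_trim_mm, ~f_sim_n, ~c_kpa, ~m,
    ~c_lo_kpa, ~c_hi_kpa, ~m_lo, ~m_hi, ~min_f_fu_tot,
    "R1", 20, 0.5, 10.78,   5, 30,  5,   8, 24, 60, 0.43,
    "R2", 25, 0.6, 13.11,   7, 17,  6,   7, 15, 39, 0.33,
    "R3", 25, 0.5,  9.62,   7, 12,  6,   7, 11, 32, 0.38,
    "R4", 25, 0.5, 11.24,   6, 17,  5,   7, 15, 35, 0.31,
    "R5", 25, 0.6, 12.46,   8, 14,  6,   8, 13, 38, 0.35,
    "R6", 16, 0.6, 19.60,  25, 19, 20,  29, 16, 39, 0.12,
    "A1", 16, 0.6, 17.08,  18, 25, 17,  18, 21, 59, 0.26,
    "A2", 20, 0.5, 30.37,  19, 24, 17,  24, 20, 44, 0.29,
    "A3", 20, 0.5, 23.91,  20, 18, 18,  22, 17, 29, 0.13,
    "A4", 20, 0.5, 21.07,  16, 20, 15,  19, 17, 44, 0.26,
    "A5", 20, 0.6, 21.07,  16, 20, 12,  16, 16, 60, 0.33,
    "A6", 13, 0.4, 59.48, 100, 23, 78, 126, 16, 44, 0.34
  )
}
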