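#' Polynomial force-displacement fit objects
#'
#' A `polyfit` represents a through-origin polynomial description `f(delta)`
#' of an indenter force-displacement curve: coefficients in descending powers
#' (units N/mm^k), a validity range `0 <= delta <= delta_max`, and the
#' goodness of fit. All region-mean abdominal curves pass through the origin,
#' so the constant term is always zero.
#'
#' @param coefficients Numeric vector of coefficients in descending powers,
#'   including the (zero) constant term.
#' @param delta_max_mm Upper end of the validity range in mm.
#' @param rmse Root-mean-square residual of the fit (as reported alongside
#'   the bundled reference fits).
#' @param r_squared Coefficient of determination.
#' @param region Optional region label.
#' @return An object of class `polyfit`.
#' @export
new_polyfit <- function(coefficients, delta_max_mm, rmse = NA_real_,
                        r_squared = NA_real_, region = NA_character_) {
  coefficients <- as.numeric(coefficients)
  assert_that(length(coefficients) >= 2, "a polyfit needs degree >= 1")
  assert_that(all(is.finite(coefficients)), "non-finite fit coefficients")
  assert_that(
    abs(coefficients[length(coefficients)]) < 1e-12,
    "force-displacement fits must pass through the origin (constant term 0)"
  )
  assert_that(is.finite(delta_max_mm) && delta_max_mm > 0,
              "delta_max must be positive")
  structure(
    list(
      coefficients = coefficients,
      degree = length(coefficients) - 1L,
      delta_max_mm = as.numeric(delta_max_mm),
      rmse = rmse,
      r_squared = r_squared,
      region = region
    ),
    class = "polyfit"
  )
}

#' Coerce a reference-table row to a polyfit
#'
#' @param row A one-row tibble as returned by [reference_force_fits()], or a
#'   region label to look up in that table.
#' @return A [new_polyfit()] object.
#' @export
as_polyfit <- function(row) {
  if (is.character(row) && length(row) == 1L) {
    tab <- reference_force_fits()
    row <- tab[tab$region == row, ]
    assert_that(nrow(row) == 1L, "unknown region label")
  }
  new_polyfit(row$coefficients[[1]], row$delta_max_mm, rmse = row$rmse,
              region = row$region)
}

#' @export
print.polyfit <- function(x, ...) {
  cat(sprintf(
    "<polyfit> degree %d%s, valid 0..%.4g mm, rmse %.4g\n",
    x$degree,
    if (!is.na(x$region)) paste0(" [", x$region, "]") else "",
    x$delta_max_mm, x$rmse
  ))
  cat("  coefficients (descending):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Clean a raw indenter force-displacement record
#'
#' Removes samples recorded before a detectable contact force and after
#' maximum stroke, and drops recording-related outliers. A sample counts as
#' pre-contact while the force has not yet exceeded `contact_threshold_n`;
#' samples beyond the maximum recorded displacement (the end of the loading
#' stroke) are discarded. Outliers are samples whose force deviates by more
#' than `mad_k` robust standard deviations from a centered rolling median of
#' the force trace.
#'
#' @param data A tibble with at least columns `delta_mm` (non-decreasing
#'   indenter displacement) and `force_n`.
#' @param contact_threshold_n Contact detection threshold in N.
#' @param max_stroke_mm Maximum stroke; defaults to the largest recorded
#'   displacement.
#' @param mad_k Outlier cut in multiples of the rolling MAD.
#' @param mad_window Rolling-median window length (odd).
#' @return The cleaned tibble (same columns).
#' @export
clean_record <- function(data, contact_threshold_n = 0.1,
                         max_stroke_mm = NULL, mad_k = 5, mad_window = 11L) {
  assert_that(all(c("delta_mm", "force_n") %in% names(data)),
              "need columns delta_mm and force_n")
  assert_that(nrow(data) >= 2, "need at least 2 samples")
  d <- data
  # pre-contact prefix: everything before the force first exceeds threshold
  idx <- which(d$force_n > contact_threshold_n)
  assert_that(length(idx) > 0, "no sample above the contact threshold: unusable trial")
  d <- d[idx[1]:nrow(d), , drop = FALSE]
  # beyond maximum stroke
  max_stroke_mm <- max_stroke_mm %||% max(d$delta_mm)
  d <- d[d$delta_mm <= max_stroke_mm + 1e-12, , drop = FALSE]
  # recording-related outliers: > mad_k * MAD from a centered rolling median
  if (nrow(d) >= mad_window) {
    f <- d$force_n
    n <- length(f)
    half <- (mad_window - 1L) %/% 2L
    # symmetric (shrinking near the ends) windows: the median of a
    # monotone window is then its center sample, so clean ramps are
    # left untouched
    med <- vapply(seq_len(n), function(i) {
      hi <- min(half, i - 1L, n - i)
      median(f[(i - hi):(i + hi)])
    }, numeric(1))
    dev <- abs(f - med)
    # floor keeps the cut meaningful on noiseless monotone records, where
    # the rolling-median deviation is exactly zero
    sigma <- max(median(dev) * 1.4826, 1e-3 * diff(range(f)))
    if (sigma > 0) d <- d[dev <= mad_k * sigma, , drop = FALSE]
  }
  assert_that(nrow(d) >= 2, "record empty after cleaning: unusable trial")
  d
}

# Through-origin least-squares polynomial of fixed degree; returns
# coefficients (descending, constant 0), rmse, r2.
fit_origin_poly <- function(delta, force, degree) {
  X <- vapply(seq(degree, 1L), function(k) delta^k, numeric(length(delta)))
  X <- matrix(X, ncol = degree)
  fit <- lm.fit(X, force)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  resid <- force - X %*% cf
  rmse <- sqrt(mean(resid^2))
  ss_tot <- sum((force - mean(force))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  list(coefficients = c(cf, 0), rmse = rmse, r_squared = r2)
}

#' Fit a through-origin polynomial force-displacement curve
#'
#' Fits polynomials of degree 1..`max_degree` through the origin to pooled
#' (cleaned) force-displacement samples and keeps the least possible degree
#' with minimum RMSE: the smallest degree whose RMSE is within `rmse_tol`
#' (multiplicative) of the best RMSE over all candidate degrees. A strict
#' minimum would always select the largest degree, so a small tolerance is
#' what makes "least possible degree" meaningful.
#'
#' @param data One record or several pooled records (tibble with `delta_mm`,
#'   `force_n`), or a list of such tibbles.
#' @param max_degree Largest degree to consider (1-5).
#' @param rmse_tol Multiplicative RMSE tolerance for degree selection.
#' @param region Optional region label stored on the result.
#' @return A [new_polyfit()] object with `delta_max_mm` set from the pooled
#'   data.
#' @export
#' @examples
#' d <- tibble::tibble(delta_mm = seq(0, 30, 0.5),
#'                     force_n = 8.604e-3 * delta_mm^2 + 0.126 * delta_mm)
#' fit_force_displacement(d)
fit_force_displacement <- function(data, max_degree = 5L, rmse_tol = 1.01,
                                   region = NA_character_) {
  if (is.data.frame(data)) data <- list(data)
  delta <- unlist(lapply(data, `[[`, "delta_mm"))
  force <- unlist(lapply(data, `[[`, "force_n"))
  keep <- is.finite(delta) & is.finite(force)
  delta <- delta[keep]; force <- force[keep]
  assert_that(length(delta) >= 2, "need at least 2 pooled samples")
  max_degree <- min(as.integer(max_degree), 5L)
  # degree capped so the system stays overdetermined
  max_degree <- max(1L, min(max_degree, length(delta) - 1L))
  fits <- lapply(seq_len(max_degree), function(n) fit_origin_poly(delta, force, n))
  rmses <- vapply(fits, `[[`, numeric(1), "rmse")
  best <- min(rmses)
  # absolute guard keeps "least possible degree" meaningful when the data
  # are (numerically) exactly polynomial and every RMSE is ~0
  pick <- which(rmses <= rmse_tol * best + 1e-9 * max(abs(force)))[1]
  f <- fits[[pick]]
  assert_that(all(is.finite(f$coefficients)), "non-finite fit coefficients")
  new_polyfit(f$coefficients, delta_max_mm = max(delta), rmse = f$rmse,
              r_squared = f$r_squared, region = region)
}

#' Evaluate a force-displacement fit
#'
#' Horner evaluation of the stored descending coefficients. The fit is only
#' declared valid on `0 <= delta <= delta_max`; evaluation outside signals an
#' error rather than extrapolating.
#'
#' @param fit A `polyfit`.
#' @param delta_mm Displacement(s) in mm.
#' @param tol Tolerance on the range check.
#' @return Force(s) in N.
#' @export
evaluate_fit <- function(fit, delta_mm, tol = 1e-8) {
  stopifnot(inherits(fit, "polyfit"))
  assert_that(all(delta_mm >= -tol & delta_mm <= fit$delta_max_mm + tol),
              "delta outside the fit's validity range (no extrapolation)")
  poly_eval(fit$coefficients, delta_mm)
}

#' Upper and lower range boundaries of a region's pooled curves
#'
#' Builds conforming 2D boundaries of the pooled force-displacement data of
#' one region: on a displacement grid, the pointwise maximum and minimum
#' force over all pooled records are each fitted by a through-origin
#' polynomial chosen as in [fit_force_displacement()].
#'
#' @param records List of cleaned record tibbles (one per participant/trial),
#'   or a single tibble with a `participant` column to split on.
#' @param n_grid Number of displacement grid points.
#' @inheritParams fit_force_displacement
#' @return A list of class `range_boundary` with elements `upper` and
#'   `lower` (both `polyfit`), and `region`.
#' @export
range_boundaries <- function(records, n_grid = 100L, max_degree = 5L,
                             rmse_tol = 1.01, region = NA_character_) {
  if (is.data.frame(records)) {
    assert_that("participant" %in% names(records),
                "single-tibble input needs a participant column to split on")
    records <- split(records, records$participant)
  }
  delta_hi <- min(vapply(records, function(r) max(r$delta_mm), numeric(1)))
  grid <- seq(0, delta_hi, length.out = n_grid)
  # interpolate every record onto the common grid, then take envelopes
  vals <- vapply(records, function(r) {
    approx(r$delta_mm, r$force_n, xout = grid, rule = 2)$y
  }, numeric(n_grid))
  vals <- matrix(vals, nrow = n_grid)
  upper_y <- apply(vals, 1, max)
  lower_y <- apply(vals, 1, min)
  upper <- fit_force_displacement(
    tibble::tibble(delta_mm = grid, force_n = upper_y),
    max_degree = max_degree, rmse_tol = rmse_tol, region = region)
  lower <- fit_force_displacement(
    tibble::tibble(delta_mm = grid, force_n = lower_y),
    max_degree = max_degree, rmse_tol = rmse_tol, region = region)
  structure(list(upper = upper, lower = lower, region = region),
            class = "range_boundary")
}

#' Two-segment stiffness summary of a force-displacement fit
#'
#' Subdivides a (relaxed-musculature) curve at `split_fraction * delta_max`
#' and reports a secant stiffness per segment: `k1` is the secant from the
#' origin to the split point, `k2` the secant of the second segment from the
#' split point to `delta_max`.
#'
#' @param fit A `polyfit`.
#' @param split_fraction Fraction of `delta_max` at which to split.
#' @return A tibble with columns `k1_n_mm`, `k2_n_mm`, `split_mm`.
#' @export
#' @examples
#' segment_stiffness(as_polyfit("R6")) # k1 approximately 0.72 N/mm
segment_stiffness <- function(fit, split_fraction = 0.45) {
  stopifnot(inherits(fit, "polyfit"))
  assert_that(fit$delta_max_mm > 0, "delta_max must be positive")
  ds <- split_fraction * fit$delta_max_mm
  f1 <- evaluate_fit(fit, ds)
  f2 <- evaluate_fit(fit, fit$delta_max_mm)
  tibble::tibble(
    k1_n_mm = f1 / ds,
    k2_n_mm = (f2 - f1) / (fit$delta_max_mm - ds),
    split_mm = ds
  )
}

#' @export
tidy.polyfit <- function(x, ...) {
  n <- x$degree
  tibble::tibble(
    term = paste0("delta^", seq(n, 0L)),
    estimate = x$coefficients
  )
}

#' @export
glance.polyfit <- function(x, ...) {
  tibble::tibble(
    region = x$region,
    degree = x$degree,
    delta_max_mm = x$delta_max_mm,
    rmse = x$rmse,
    r_squared = x$r_squared
  )
}

#' Plot a force-displacement fit
#'
#' @param object A `polyfit`.
#' @param n Number of curve samples.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.polyfit <- function(object, n = 200L, ...) {
  d <- tibble::tibble(
    delta_mm = seq(0, object$delta_max_mm, length.out = n)
  )
  d$force_n <- evaluate_fit(object, d$delta_mm)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_mm, y = .data$force_n)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = expression(delta ~ "(mm)"), y = "f (N)",
      title = if (!is.na(object$region)) {
        paste("Mean force-displacement fit,", object$region)
      } else "Force-displacement fit"
    ) +
    ggplot2::theme_minimal()
}
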