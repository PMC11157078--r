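# internal helpers shared across modules

# Evaluate a polynomial with coefficients in descending powers by Horner's rule.
poly_eval <- function(coefficients, x) {
  out <- rep(0, length(x))
  for (ck in coefficients) out <- out * x + ck
  out
}

# Derivative coefficients (descending powers).
poly_deriv <- function(coefficients) {
  n <- length(coefficients) - 1L
  if (n < 1L) return(0)
  coefficients[seq_len(n)] * seq(n, 1L)
}

# Real roots of a polynomial given descending coefficients.
poly_real_roots <- function(coefficients, tol = 1e-8) {
  # strip leading zeros; polyroot wants ascending order
  nz <- which(abs(coefficients) > 0)
  if (length(nz) == 0L) return(numeric(0))
  coefficients <- coefficients[nz[1]:length(coefficients)]
  if (length(coefficients) < 2L) return(numeric(0))
  r <- polyroot(rev(coefficients))
  re <- Re(r)[abs(Im(r)) < tol * (1 + abs(Re(r)))]
  sort(re)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}
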